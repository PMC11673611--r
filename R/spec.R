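#' Define a measurement/structural model specification
#'
#' Describes the graph of a quantile (or mean) structural equation model:
#' which observed indicator measures which latent factor, which loading per
#' factor is pinned to 1 for identification, which columns are observed
#' covariates of the structural equation, and the quantile grid.  Factor 1 is
#' always the endogenous factor; factors 2..(q2+1) are exogenous.
#'
#' @param indicators character vector of indicator column names (length p).
#' @param factor_map integer vector (length p) assigning each indicator to a
#'   factor, 1 = endogenous, 2..q2+1 = exogenous.
#' @param factor_names character vector naming the factors (length q2 + 1).
#' @param fixed_loadings integer vector of indicator indices whose loading is
#'   fixed at 1 (exactly one per factor).  Default: the first indicator of
#'   each factor.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param quantile_grid numeric vector of quantile levels in (0, 1).
#' @param scale_min,scale_max numeric vectors (recycled) giving admissible
#'   bounds for each indicator then covariate column, used by
#'   [read_survey_csv()] and by the generator's discretization.
#' @param include_intercepts logical; if `FALSE` (default) indicators are
#'   centered at their sample means before fitting, if `TRUE` measurement
#'   intercepts are estimated under a vague normal prior.
#' @return An object of class `bqsem_spec`.
#' @seealso [lss_template()] for the bundled 20-indicator life-satisfaction
#'   survey layout, [validate_spec()] for the invariant checks.
#' @export
model_spec <- function(indicators, factor_map, factor_names,
                       fixed_loadings = NULL,
                       covariates = character(),
                       quantile_grid = c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95),
                       scale_min = 1, scale_max = 5,
                       include_intercepts = FALSE) {
  p <- length(indicators)
  if (is.null(fixed_loadings))
    fixed_loadings <- vapply(sort(unique(factor_map)),
                             function(f) which(factor_map == f)[1L], 1L)
  spec <- structure(list(
    indicators = as.character(indicators),
    factor_map = as.integer(factor_map),
    factor_names = as.character(factor_names),
    fixed_loadings = as.integer(fixed_loadings),
    covariates = as.character(covariates),
    quantile_grid = as.numeric(quantile_grid),
    scale_min = rep_len(as.numeric(scale_min), p + length(covariates)),
    scale_max = rep_len(as.numeric(scale_max), p + length(covariates)),
    include_intercepts = isTRUE(include_intercepts)
  ), class = "bqsem_spec")
  validate_spec(spec)
}

#' Number of exogenous factors in a specification
#' @param spec a `bqsem_spec`.
#' @return integer count of exogenous factors.
#' @export
n_exogenous <- function(spec) length(spec$factor_names) - 1L

#' Free (estimated) loadings of a specification
#' @param spec a `bqsem_spec`.
#' @return integer vector of indicator indices with estimated loadings.
#' @export
free_loadings <- function(spec)
  setdiff(seq_along(spec$indicators), spec$fixed_loadings)

#' Validate a model specification (and optionally priors)
#'
#' Checks the structural invariants: every indicator maps to exactly one
#' declared factor, every factor has at least one indicator exactly one of
#' which has a fixed loading, and all quantile levels lie strictly inside
#' (0, 1).  When `priors` is supplied its positivity/shape constraints are
#' checked too.
#'
#' @param spec a `bqsem_spec`.
#' @param priors optional `bqsem_priors`.
#' @return `spec`, invisibly usable, after passing all checks.
#' @export
validate_spec <- function(spec, priors = NULL) {
  p <- length(spec$indicators)
  q <- length(spec$factor_names)
  if (length(spec$factor_map) != p)
    stop("factor_map must assign every indicator to a factor", call. = FALSE)
  if (any(is.na(spec$factor_map)) || any(spec$factor_map < 1L) ||
      any(spec$factor_map > q))
    stop("indicator mapped to no declared factor", call. = FALSE)
  for (f in seq_len(q)) {
    members <- which(spec$factor_map == f)
    if (length(members) == 0L)
      stop("factor '", spec$factor_names[f], "' has no indicators",
           call. = FALSE)
    nfix <- sum(spec$fixed_loadings %in% members)
    if (nfix != 1L)
      stop("identification error: factor '", spec$factor_names[f],
           "' must have exactly one loading fixed at 1 (found ", nfix, ")",
           call. = FALSE)
  }
  assert_tau(spec$quantile_grid)
  if (is.unsorted(spec$quantile_grid, strictly = TRUE))
    stop("quantile_grid must be strictly increasing", call. = FALSE)
  if (!is.null(priors)) validate_priors(priors, n_exogenous(spec))
  spec
}

#' Prior hyperparameters for BSEM/BQSEM
#'
#' Defaults follow the standard vague prior structure for these models:
#' conjugate normal priors with mean 1 and variance 10,000 on free loadings,
#' inverse-gamma(9, 4) on measurement error variances and on the structural
#' error scale (the normal variance in mean mode, the asymmetric-Laplace
#' scale in quantile mode), inverse-Wishart(6, 15 I) on the exogenous factor
#' covariance, and normal(0, 10,000) on structural coefficients.
#'
#' @param loading_prior_mean,loading_prior_variance normal prior on each free
#'   loading.
#' @param error_var_shape,error_var_rate inverse-gamma prior on measurement
#'   error variances.
#' @param structural_scale_shape,structural_scale_rate inverse-gamma prior on
#'   the structural error scale.
#' @param wishart_df inverse-Wishart degrees of freedom for the factor
#'   covariance (must exceed q2 - 1).
#' @param wishart_scale inverse-Wishart scale matrix, or a scalar c meaning
#'   c times the identity (dimension resolved when fitting).
#' @param coef_prior_mean,coef_prior_variance normal prior on structural
#'   coefficients (and measurement intercepts when estimated).
#' @return An object of class `bqsem_priors`.
#' @export
prior_spec <- function(loading_prior_mean = 1,
                       loading_prior_variance = 10000,
                       error_var_shape = 9, error_var_rate = 4,
                       structural_scale_shape = 9, structural_scale_rate = 4,
                       wishart_df = 6, wishart_scale = 15,
                       coef_prior_mean = 0, coef_prior_variance = 10000) {
  structure(list(
    loading_prior_mean = loading_prior_mean,
    loading_prior_variance = loading_prior_variance,
    error_var_shape = error_var_shape, error_var_rate = error_var_rate,
    structural_scale_shape = structural_scale_shape,
    structural_scale_rate = structural_scale_rate,
    wishart_df = wishart_df, wishart_scale = wishart_scale,
    coef_prior_mean = coef_prior_mean,
    coef_prior_variance = coef_prior_variance
  ), class = "bqsem_priors")
}

validate_priors <- function(priors, q2) {
  pos <- c("loading_prior_variance", "error_var_shape", "error_var_rate",
           "structural_scale_shape", "structural_scale_rate",
           "coef_prior_variance")
  for (nm in pos)
    if (!is.numeric(priors[[nm]]) || priors[[nm]] <= 0)
      stop(nm, " must be strictly positive", call. = FALSE)
  if (q2 > 0) {
    if (priors$wishart_df <= q2 - 1)
      stop("wishart_df must exceed q2 - 1", call. = FALSE)
    R0 <- resolve_wishart_scale(priors$wishart_scale, q2)
    ev <- eigen(R0, symmetric = TRUE, only.values = TRUE)$values
    if (any(abs(R0 - t(R0)) > 1e-10) || any(ev <= 0))
      stop("wishart_scale must be symmetric positive definite", call. = FALSE)
  }
  invisible(priors)
}

resolve_wishart_scale <- function(ws, q2) {
  if (is.matrix(ws)) {
    if (!all(dim(ws) == c(q2, q2)))
      stop("wishart_scale matrix must be ", q2, " x ", q2, call. = FALSE)
    ws
  } else {
    diag(as.numeric(ws), q2)
  }
}

#' The LSS-2020 survey model template
#'
#' The bundled 20-indicator, 6-factor, 3-covariate layout: an endogenous
#' subjective well-being factor measured by happiness (1-5) and overall life
#' satisfaction (0-10), and five exogenous satisfaction factors
#' (housing-district, work life, social life, relationships, public
#' services) measured by 18 further 5-point items, with health, education and
#' marriage satisfaction (1-5) as observed covariates.  One loading per
#' factor (its first indicator) is fixed at 1, leaving 14 free loadings.
#'
#' @inheritParams model_spec
#' @return A `bqsem_spec`.
#' @export
lss_template <- function(quantile_grid = c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95),
                         include_intercepts = FALSE) {
  indicators <- c("happiness", "life_satisfaction",
                  "housing", "district",
                  "work", "earning", "income", "time", "colleague",
                  "social_life", "personal_time",
                  "relative", "friend", "neighbor",
                  "health_service", "public_order", "judicial",
                  "education_service", "ssi", "transportation")
  factor_map <- c(1, 1, 2, 2, 3, 3, 3, 3, 3, 4, 4, 5, 5, 5, 6, 6, 6, 6, 6, 6)
  factor_names <- c("swb", "housing_district", "work_life", "social_life_f",
                    "relationships", "public_service")
  covariates <- c("health_sat", "education_sat", "marriage_sat")
  scale_min <- c(1, 0, rep(1, 18), rep(1, 3))
  scale_max <- c(5, 10, rep(5, 18), rep(5, 3))
  model_spec(indicators, factor_map, factor_names,
             covariates = covariates,
             quantile_grid = quantile_grid,
             scale_min = scale_min, scale_max = scale_max,
             include_intercepts = include_intercepts)
}

#' @export
print.bqsem_spec <- function(x, ...) {
  cat("bqsem model specification\n")
  cat("  indicators:", length(x$indicators),
      " factors:", length(x$factor_names),
      " (1 endogenous + ", n_exogenous(x), " exogenous)\n", sep = "")
  cat("  free loadings:", length(free_loadings(x)),
      " covariates:", length(x$covariates), "\n")
  cat("  quantile grid:", paste(x$quantile_grid, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a model + prior configuration file
#'
#' Serializes a `bqsem_spec` and `bqsem_priors` pair to a nested YAML file
#' (and back), so an analysis can be pinned to a config under version
#' control.
#'
#' @param spec a `bqsem_spec`.
#' @param priors a `bqsem_priors`.
#' @param path file path.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns `list(spec =, priors =)`.
#' @export
write_model_config <- function(spec, priors, path) {
  obj <- list(
    model = list(
      indicators = spec$indicators,
      factor_map = spec$factor_map,
      factor_names = spec$factor_names,
      fixed_loadings = spec$fixed_loadings,
      covariates = spec$covariates,
      quantile_grid = spec$quantile_grid,
      scale_min = spec$scale_min,
      scale_max = spec$scale_max,
      include_intercepts = spec$include_intercepts
    ),
    priors = unclass(priors)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  obj <- yaml::read_yaml(path)
  m <- obj$model
  spec <- model_spec(m$indicators, m$factor_map, m$factor_names,
                     fixed_loadings = m$fixed_loadings,
                     covariates = if (is.null(m$covariates)) character() else m$covariates,
                     quantile_grid = m$quantile_grid,
                     scale_min = m$scale_min, scale_max = m$scale_max,
                     include_intercepts = m$include_intercepts)
  priors <- do.call(prior_spec, obj$priors)
  list(spec = spec, priors = priors)
}
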