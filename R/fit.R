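#' MCMC settings
#'
#' Single-chain Gibbs protocol.  Defaults are the protocol used throughout
#' the package's analyses: 10,000 iterations with the first 2,000 discarded
#' as burn-in, no thinning.
#'
#' @param n_iterations total Gibbs sweeps.
#' @param burn_in sweeps discarded before summarization (`< n_iterations`).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed; a fixed seed makes the chain bit-reproducible.
#' @param score_keep number of retained sweeps (evenly spaced) at which the
#'   latent factor scores are additionally stored, for posterior predictive
#'   checks.  Use 0 to store none.
#' @return An object of class `mcmc_control`.
#' @export
mcmc_control <- function(n_iterations = 10000, burn_in = 2000, thin = 1,
                         seed = 1, score_keep = 200) {
  if (burn_in >= n_iterations)
    stop("burn_in must be smaller than n_iterations", call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 seed = as.integer(seed),
                 score_keep = as.integer(score_keep)),
            class = "mcmc_control")
}

parameter_names <- function(spec) {
  p <- length(spec$indicators)
  r <- length(spec$covariates)
  q2 <- n_exogenous(spec)
  free <- free_loadings(spec)
  nm <- c(sprintf("lambda[%d,%d]", free, spec$factor_map[free]),
          paste0("b", 0:r),
          if (q2 > 0) paste0("gamma", seq_len(q2)))
  if (q2 > 0)
    for (j in seq_len(q2))
      nm <- c(nm, sprintf("phi[%d,%d]", j, seq_len(j)))
  nm <- c(nm, "sigma_delta", sprintf("psi[%d]", seq_len(p)))
  if (spec$include_intercepts) nm <- c(nm, sprintf("mu[%d]", seq_len(p)))
  nm
}

prepare_fit_inputs <- function(data, spec, center_covariates) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(spec$indicators, spec$covariates), names(data))
  if (length(missing_cols) > 0)
    stop("data is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  Y <- as.matrix(data[, spec$indicators, drop = FALSE])
  D <- as.matrix(data[, spec$covariates, drop = FALSE])
  storage.mode(Y) <- "double"; storage.mode(D) <- "double"
  n <- nrow(Y)
  centers <- if (n > 0 && !spec$include_intercepts) colMeans(Y) else
    rep(0, ncol(Y))
  Yc <- sweep(Y, 2, centers)
  dcenters <- if (n > 0 && center_covariates && ncol(D) > 0) colMeans(D) else
    rep(0, ncol(D))
  Dc <- if (ncol(D) > 0) sweep(D, 2, dcenters) else D
  list(Y = Yc, D = Dc, centers = centers, dcenters = dcenters)
}

fit_sem_engine <- function(data, spec, priors, mcmc, quantile, tau,
                           fixed_psi, fixed_sigma, center_covariates,
                           init = NULL) {
  validate_spec(spec, priors)
  if (quantile) assert_tau(tau)
  stopifnot(inherits(mcmc, "mcmc_control"))
  q2 <- n_exogenous(spec)
  inp <- prepare_fit_inputs(data, spec, center_covariates)
  p <- length(spec$indicators)

  fp <- rep(NA_real_, p)
  if (!is.null(fixed_psi)) {
    fixed_psi <- rep_len(as.numeric(fixed_psi), p)
    fp <- fixed_psi
  }
  fs <- if (is.null(fixed_sigma)) NA_real_ else as.numeric(fixed_sigma)

  pr <- unclass(priors)
  pr$wishart_scale <- resolve_wishart_scale(priors$wishart_scale, max(q2, 1))

  n_keep <- (mcmc$n_iterations - mcmc$burn_in) %/% mcmc$thin
  score_rows <- integer(0)
  if (mcmc$score_keep > 0 && nrow(inp$Y) > 0)
    score_rows <- unique(round(seq(1, n_keep,
                                   length.out = min(mcmc$score_keep, n_keep))))

  fixed <- as.integer(seq_along(spec$indicators) %in% spec$fixed_loadings)

  set.seed(mcmc$seed)
  t0 <- proc.time()[["elapsed"]]
  out <- .gibbs_sem(inp$Y, inp$D, as.integer(spec$factor_map), fixed,
                    as.integer(q2), quantile,
                    if (quantile) tau else 0.5,
                    pr, unclass(mcmc), fp, fs,
                    spec$include_intercepts, as.integer(score_rows),
                    if (is.null(init)) list() else init)
  runtime <- proc.time()[["elapsed"]] - t0

  draws <- out$draws
  colnames(draws) <- parameter_names(spec)
  if (any(!is.finite(draws)))
    stop("divergent draw encountered (non-finite value in chain); ",
         "check data scaling and priors", call. = FALSE)

  structure(list(
    draws = draws,
    scores = out$scores,           # n x q x length(score_rows)
    score_rows = score_rows,
    spec = spec, priors = priors, mcmc = mcmc,
    mode = if (quantile) "quantile" else "mean",
    tau = if (quantile) tau else NA_real_,
    Y = inp$Y, D = inp$D,
    centers = inp$centers, dcenters = inp$dcenters,
    fixed_psi = fp, fixed_sigma = fs,
    state = out$state,
    runtime = runtime
  ), class = "bqsem_fit")
}

#' Fit the mean-based Bayesian SEM
#'
#' Gaussian measurement model plus a Gaussian structural equation for the
#' conditional mean of the endogenous factor, estimated by single-chain
#' Gibbs sampling with conjugate full conditionals (normal draws for
#' loadings, coefficients and latent scores, inverse-gamma for variances,
#' inverse-Wishart for the exogenous factor covariance).
#'
#' Indicators are centered at their sample means before fitting unless the
#' specification asks for estimated measurement intercepts; covariates are
#' centered when `center_covariates = TRUE` (slopes are unaffected, only the
#' structural intercept changes meaning).
#'
#' @param data data frame holding the indicator and covariate columns named
#'   in `spec`.
#' @param spec a [model_spec()] / [lss_template()] object.
#' @param priors a [prior_spec()] object.
#' @param mcmc an [mcmc_control()] object.
#' @param fixed_psi optional scalar/vector of measurement error variances to
#'   hold fixed instead of estimating (used e.g. to reduce the model to an
#'   observed-variable regression).
#' @param fixed_sigma optional fixed structural error scale.
#' @param center_covariates logical, default `TRUE`.
#' @return A `bqsem_fit`: retained draws (matrix, one named column per free
#'   parameter), thinned latent-score draws, and the inputs/config needed to
#'   reproduce or extend the run.
#' @export
fit_bsem <- function(data, spec, priors = prior_spec(),
                     mcmc = mcmc_control(),
                     fixed_psi = NULL, fixed_sigma = NULL,
                     center_covariates = TRUE) {
  fit_sem_engine(data, spec, priors, mcmc, quantile = FALSE, tau = NA,
                 fixed_psi = fixed_psi, fixed_sigma = fixed_sigma,
                 center_covariates = center_covariates)
}

#' Fit the Bayesian quantile SEM
#'
#' Same Gaussian measurement side as [fit_bsem()] (the measurement model is
#' kept at the median-consistent Gaussian form across all quantile levels),
#' but the structural error follows an asymmetric Laplace working likelihood
#' whose `tau`-quantile is zero, so the structural coefficients describe the
#' `tau`-th conditional quantile of the endogenous factor.  The ALD enters
#' through its normal-exponential mixture: one exponential mixing latent per
#' subject keeps every full conditional conjugate.
#'
#' @inheritParams fit_bsem
#' @param tau quantile level in (0, 1).
#' @return A `bqsem_fit` (see [fit_bsem()]); the structural coefficients in
#'   `draws` are tau-specific.
#' @export
fit_bqsem <- function(data, spec, tau, priors = prior_spec(),
                      mcmc = mcmc_control(),
                      fixed_psi = NULL, fixed_sigma = NULL,
                      center_covariates = TRUE) {
  fit_sem_engine(data, spec, priors, mcmc, quantile = TRUE, tau = tau,
                 fixed_psi = fixed_psi, fixed_sigma = fixed_sigma,
                 center_covariates = center_covariates)
}

#' Initial parameter state for the Gibbs sampler
#'
#' The deterministic starting state the fitters use: loadings, variances and
#' the structural scale at 1, coefficients at 0, factor covariance at
#' identity, latent scores at per-factor indicator means (of the centered
#' data), mixing latents at 1.
#'
#' @param data data frame with the spec's columns.
#' @param spec a `bqsem_spec`.
#' @param center_covariates logical, as in [fit_bsem()].
#' @return A named list (`loadings`, `psi`, `sigma`, `beta`, `Phi`, `omega`,
#'   `z`, `mu`) usable as `state` in [gibbs_step()].
#' @export
initial_state <- function(data, spec, center_covariates = TRUE) {
  inp <- prepare_fit_inputs(data, spec, center_covariates)
  p <- length(spec$indicators)
  q2 <- n_exogenous(spec)
  omega <- sapply(seq_len(q2 + 1), function(f)
    rowMeans(inp$Y[, spec$factor_map == f, drop = FALSE]))
  if (nrow(inp$Y) == 0) omega <- matrix(0, 0, q2 + 1)
  list(loadings = rep(1, p), psi = rep(1, p), sigma = 1,
       beta = rep(0, 1 + length(spec$covariates) + q2),
       Phi = diag(q2), omega = matrix(omega, nrow(inp$Y), q2 + 1),
       z = rep(1, nrow(inp$Y)), mu = rep(0, p))
}

#' One full Gibbs sweep
#'
#' Runs a single sweep of the sampler from an explicit parameter state and
#' returns the updated state: latent scores, mixing latents (quantile mode),
#' free loadings, measurement error variances, structural coefficients,
#' structural scale, factor covariance, in that fixed order.  Each update is
#' an exact draw from its full conditional.  Mostly useful for testing and
#' for custom chain schedules; [fit_bsem()]/[fit_bqsem()] run the same sweep
#' internally.
#'
#' @param state a state list as produced by [initial_state()] or a previous
#'   `gibbs_step()` call (also available as `$state` of a `bqsem_fit`).
#' @param data,spec,priors as in [fit_bsem()].
#' @param tau quantile level, or `NULL` for the mean model.
#' @param seed integer seed for the sweep's draws.
#' @param center_covariates logical, as in [fit_bsem()].
#' @return The updated state list.
#' @export
gibbs_step <- function(state, data, spec, priors = prior_spec(), tau = NULL,
                       seed = 1, center_covariates = TRUE) {
  fit <- fit_sem_engine(data, spec, priors,
                        mcmc_control(n_iterations = 1, burn_in = 0,
                                     seed = seed, score_keep = 0),
                        quantile = !is.null(tau), tau = tau,
                        fixed_psi = NULL, fixed_sigma = NULL,
                        center_covariates = center_covariates,
                        init = state)
  fit$state
}

#' Names of the structural coefficients of a fit or spec
#' @param x a `bqsem_fit` or `bqsem_spec`.
#' @return character vector `b0, b1, ..., gamma1, ...`.
#' @export
structural_names <- function(x) {
  spec <- if (inherits(x, "bqsem_fit")) x$spec else x
  r <- length(spec$covariates)
  q2 <- n_exogenous(spec)
  c(paste0("b", 0:r), if (q2 > 0) paste0("gamma", seq_len(q2)))
}

#' @export
print.bqsem_fit <- function(x, ...) {
  cat("Bayesian", if (x$mode == "quantile")
    sprintf("quantile SEM (tau = %.2f)", x$tau) else "SEM (mean model)", "\n")
  cat(sprintf("  n = %d, %d retained draws (%d iterations, %d burn-in, thin %d), seed %d\n",
              nrow(x$Y), nrow(x$draws), x$mcmc$n_iterations, x$mcmc$burn_in,
              x$mcmc$thin, x$mcmc$seed))
  b <- colMeans(x$draws[, structural_names(x), drop = FALSE])
  cat("  structural posterior means:\n")
  print(round(b, 3))
  invisible(x)
}

#' Export retained draws with a metadata sidecar
#'
#' Writes the retained chain to CSV (one row per retained sweep, one column
#' per parameter) and a JSON sidecar recording mode, tau, seed, MCMC
#' protocol and runtime.
#'
#' @param fit a `bqsem_fit`.
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  write.csv(as.data.frame(fit$draws), path, row.names = FALSE)
  meta <- list(mode = fit$mode, tau = fit$tau,
               seed = fit$mcmc$seed,
               n_iterations = fit$mcmc$n_iterations,
               burn_in = fit$mcmc$burn_in, thin = fit$mcmc$thin,
               n = nrow(fit$Y), runtime_seconds = round(fit$runtime, 3))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
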