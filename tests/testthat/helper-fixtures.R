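# Small model layouts used across tests; everything is generated in code.

# 6 indicators, endogenous factor + 2 exogenous factors, 1 covariate
tiny_spec <- function(quantile_grid = c(0.25, 0.5, 0.75)) {
  model_spec(indicators = paste0("y", 1:6),
             factor_map = c(1, 1, 2, 2, 3, 3),
             factor_names = c("eta", "f1", "f2"),
             covariates = "d1",
             quantile_grid = quantile_grid)
}

tiny_scenario <- function(n, seed, kappa = c(0, 0), error_scale = 0.5,
                          error_dist = "normal", ...) {
  synthetic_scenario(n = n, spec = tiny_spec(),
                     loadings = c(1, 0.8, 1, 1.2, 1, 0.7),
                     measurement_error_sd = 0.5,
                     Phi = matrix(c(0.6, 0.2, 0.2, 0.5), 2),
                     b0 = 0, b = 0.2, gamma = c(0.5, 0.3),
                     kappa = kappa, error_dist = error_dist,
                     error_scale = error_scale, seed = seed, ...)
}

# observed-outcome regression as a degenerate SEM: one indicator pinned to
# the endogenous factor with (near) zero measurement noise, no exogenous
# factors, regressors entering as covariates
latent_free_spec <- function(r) {
  model_spec(indicators = "y", factor_map = 1L, factor_names = "eta",
             covariates = paste0("x", seq_len(r)),
             scale_min = -Inf, scale_max = Inf)
}

latent_free_data <- function(n, beta, tau_fun = NULL, seed = 1) {
  set.seed(seed)
  r <- length(beta) - 1
  X <- matrix(rnorm(n * r), n, r, dimnames = list(NULL, paste0("x", 1:r)))
  y <- beta[1] + drop(X %*% beta[-1]) + rnorm(n)
  data.frame(y = y, X)
}

# exact check-loss minimizer by enumeration: some optimal quantile
# regression line passes through m = ncol(X)+1 data points, so trying every
# point subset finds the global minimum on tiny problems
enumerate_quantreg <- function(y, X, tau) {
  X1 <- cbind(1, as.matrix(X))
  m <- ncol(X1)
  n <- length(y)
  best <- NULL; best_loss <- Inf
  for (idx in utils::combn(n, m, simplify = FALSE)) {
    A <- X1[idx, , drop = FALSE]
    if (abs(det(A)) < 1e-10) next
    b <- solve(A, y[idx])
    loss <- sum(check_function(y - X1 %*% b, tau))
    if (loss < best_loss - 1e-12) { best_loss <- loss; best <- b }
  }
  list(coefficients = drop(best), loss = best_loss)
}
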