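#' Frequentist check-function quantile regression
#'
#' Minimizes the check (pinball) loss `sum rho_tau(y - X b)` over `b`.  Used
#' as the independent frequentist benchmark for the Bayesian quantile
#' sampler: with vague priors the ALD posterior concentrates at this
#' minimizer.
#'
#' The piecewise-linear objective is optimized by BFGS on a smoothed convex
#' surrogate `(tau - 1) u + eps * log(1 + exp(u / eps))` with a continuation
#' schedule driving `eps` to 1e-6; the surrogate's gradient is exact, the
#' smoothing bias is O(eps) and negligible at the final level.
#'
#' @param y numeric response vector.
#' @param X design matrix; an intercept column is prepended unless
#'   `intercept = FALSE`.
#' @param tau quantile level in (0, 1).
#' @param intercept logical.
#' @return list with `coefficients` (named vector) and `loss` (check loss at
#'   the solution).
#' @export
check_quantreg <- function(y, X, tau, intercept = TRUE) {
  assert_tau(tau)
  X <- as.matrix(X)
  if (intercept) X <- cbind(`(intercept)` = 1, X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  b <- qr.solve(crossprod(X) + 1e-10 * diag(ncol(X)), crossprod(X, y))
  for (eps in c(1, 0.1, 0.01, 1e-3, 1e-4, 1e-6)) {
    fn <- function(beta) {
      u <- (y - X %*% beta) / eps
      # stable eps*log(1+exp(u)): eps*(max(u,0) + log1p(exp(-|u|)))
      sum((tau - 1) * (y - X %*% beta) +
            eps * (pmax(u, 0) + log1p(exp(-abs(u)))))
    }
    gr <- function(beta) {
      u <- (y - X %*% beta) / eps
      w <- (tau - 1) + 1 / (1 + exp(-u))   # d loss / d residual
      -drop(crossprod(X, w))
    }
    opt <- stats::optim(b, fn, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    b <- opt$par
  }
  b <- drop(b)
  names(b) <- colnames(X)
  list(coefficients = b, loss = sum(check_function(y - X %*% b, tau)))
}
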