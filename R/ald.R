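#' Quantile check (pinball) loss
#'
#' `rho_tau(u) = u * (tau - 1\{u < 0\})`, the loss whose minimizer over a
#' linear predictor is the tau-th conditional quantile.  The asymmetric
#' Laplace log-density is `-rho_tau(u)/scale` up to a constant, so this is
#' also the exponent of the working likelihood used by [fit_bqsem()].
#'
#' @param u numeric vector of residuals.
#' @param tau quantile level in (0, 1).
#' @return Nonnegative numeric vector, zero exactly where `u == 0`.
#' @examples
#' check_function(2, 0.5)    # 1
#' check_function(-1, 0.25)  # 0.75
#' @export
check_function <- function(u, tau) {
  assert_tau(tau)
  u * (tau - (u < 0))
}

assert_tau <- function(tau) {
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0) || any(tau >= 1))
    stop("tau must lie in the open interval (0, 1)", call. = FALSE)
  invisible(tau)
}

assert_scale <- function(scale) {
  if (!is.numeric(scale) || any(!is.finite(scale)) || any(scale <= 0))
    stop("scale must be strictly positive", call. = FALSE)
  invisible(scale)
}

#' Asymmetric Laplace distribution
#'
#' Density, log-density, distribution function, quantile function and random
#' generation for the asymmetric Laplace distribution ALD(0, scale, tau)
#' parameterized so that its density is
#' `tau * (1 - tau) / scale * exp(-rho_tau(u) / scale)`.
#' Its tau-quantile is exactly 0, which is the one distributional assumption
#' the quantile structural model places on its error term.
#'
#' `rald()` draws through the normal-exponential scale mixture
#' (`delta = k1 z + sqrt(k2 scale z) w`, `z ~ Exp(mean scale)`,
#' `w ~ N(0,1)`), the same augmentation the Gibbs sampler uses, so it doubles
#' as a check that the mixture marginal really is the ALD.
#'
#' @param u,q numeric vector of evaluation points.
#' @param p probabilities.
#' @param n number of draws.
#' @param scale positive scale parameter.
#' @param tau quantile level in (0, 1).
#' @return numeric vector.
#' @export
ald_logpdf <- function(u, scale, tau) {
  assert_scale(scale); assert_tau(tau)
  log(tau) + log(1 - tau) - log(scale) - check_function(u, tau) / scale
}

#' @rdname ald_logpdf
#' @export
ald_pdf <- function(u, scale, tau) exp(ald_logpdf(u, scale, tau))

#' @rdname ald_logpdf
#' @export
ald_cdf <- function(q, scale, tau) {
  assert_scale(scale); assert_tau(tau)
  ifelse(q <= 0,
         tau * exp((1 - tau) * q / scale),
         1 - (1 - tau) * exp(-tau * q / scale))
}

#' @rdname ald_logpdf
#' @export
ald_quantile <- function(p, scale, tau) {
  assert_scale(scale); assert_tau(tau)
  ifelse(p <= tau,
         scale / (1 - tau) * log(p / tau),
         -scale / tau * log((1 - p) / (1 - tau)))
}

#' @rdname ald_logpdf
#' @export
rald <- function(n, scale, tau) {
  assert_scale(scale); assert_tau(tau)
  k <- ald_mixture_params(tau)
  z <- stats::rexp(n, rate = 1 / scale)
  k$k1 * z + sqrt(k$k2 * scale * z) * stats::rnorm(n)
}

#' Scale-mixture constants of the asymmetric Laplace
#'
#' Constants of the normal-exponential mixture representation:
#' `k1 = (1 - 2 tau) / (tau (1 - tau))` and `k2 = 2 / (tau (1 - tau))`.
#' With `z ~ Exp(mean sigma)` and `w ~ N(0, 1)`,
#' `k1 z + sqrt(k2 sigma z) w` has marginal ALD(0, sigma, tau); conditioning
#' on `z` makes the structural equation Gaussian, which is what renders all
#' Gibbs updates conjugate.
#'
#' @inheritParams check_function
#' @return list with elements `k1` and `k2`.
#' @examples
#' ald_mixture_params(0.5)   # k1 = 0, k2 = 8
#' @export
ald_mixture_params <- function(tau) {
  assert_tau(tau)
  list(k1 = (1 - 2 * tau) / (tau * (1 - tau)),
       k2 = 2 / (tau * (1 - tau)))
}
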