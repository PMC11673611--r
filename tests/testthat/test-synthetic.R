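test_that("generation is a pure function of the scenario", {
  sc <- tiny_scenario(n = 200, seed = 99)
  g1 <- generate_survey(sc)
  g2 <- generate_survey(sc)
  expect_identical(g1, g2)
  g3 <- generate_survey(tiny_scenario(n = 200, seed = 100))
  expect_false(identical(g1$data, g3$data))
})

test_that("closed-form quantile coefficients follow the location-scale law", {
  spec <- tiny_spec()
  # homoscedastic: slopes flat in tau, intercept tracks the error quantile
  sc <- tiny_scenario(n = 10, seed = 1, kappa = c(0, 0), error_scale = 0.5)
  for (tau in c(0.1, 0.5, 0.9)) {
    co <- true_quantile_coefficients(sc, tau)
    expect_equal(unname(co[c("gamma1", "gamma2")]), c(0.5, 0.3))
    expect_equal(unname(co["b0"]), 0 + qnorm(tau, sd = 0.5))
  }
  # median of a symmetric error leaves the intercept at b0
  expect_equal(unname(true_quantile_coefficients(sc, 0.5)["b0"]), 0)
  # heteroscedastic slope at tau: gamma + kappa * F_e^{-1}(tau)
  sc2 <- tiny_scenario(n = 10, seed = 1, kappa = c(0.2, 0), error_scale = 1)
  expect_equal(unname(true_quantile_coefficients(sc2, 0.9)["gamma1"]),
               0.5 + 0.2 * qnorm(0.9))
  # skewed base error: intercept offset is that distribution's quantile
  sc3 <- tiny_scenario(n = 10, seed = 1, error_dist = "chisq3",
                       error_scale = 1)
  expect_equal(unname(true_quantile_coefficients(sc3, 0.75)["b0"]),
               (qchisq(0.75, 3) - 3) / sqrt(6))
  # matrix form over a grid
  co <- true_quantile_coefficients(sc2, c(0.25, 0.75))
  expect_equal(dim(co), c(2L, 4L))
})

test_that("generated residual quantiles match the analytic truth slice-wise", {
  sc <- tiny_scenario(n = 50000, seed = 7, kappa = c(0.3, 0))
  g <- generate_survey(sc)
  xi <- as.matrix(g$latent[, -1])
  D <- as.matrix(g$data[, "d1", drop = FALSE])
  resid <- g$latent$eta -
    (sc$b0 + drop(D %*% sc$b) + drop(xi %*% sc$gamma))
  sfac <- 1 + drop(xi %*% sc$kappa)
  expect_true(all(sfac > 0))
  # bin on the heteroscedastic factor and compare the conditional quantile
  bins <- cut(xi[, 1], quantile(xi[, 1], seq(0, 1, 0.25)),
              include.lowest = TRUE)
  for (tau in c(0.25, 0.75)) {
    emp <- tapply(resid, bins, quantile, probs = tau)
    pred <- tapply(sfac * qnorm(tau, sd = sc$error_scale), bins, mean)
    expect_equal(unname(emp), unname(pred), tolerance = 0.05)
  }
})

test_that("indicator covariance converges to the model-implied matrix", {
  sc <- tiny_scenario(n = 100000, seed = 13)
  g <- generate_survey(sc)
  Y <- as.matrix(g$data[, sc$spec$indicators])
  om <- cbind(g$latent$eta, as.matrix(g$latent[, -1]))
  lam <- sc$loadings
  fm <- sc$spec$factor_map
  implied <- diag(lam) %*% cov(om)[fm, fm] %*% diag(lam) +
    diag(sc$measurement_error_sd^2)
  expect_lt(norm(cov(Y) - implied, "F") / norm(implied, "F"), 0.05)
})

test_that("discretization respects scale bounds", {
  sc <- synthetic_scenario(n = 500, seed = 4, discretize = TRUE)
  g <- generate_survey(sc)
  spec <- sc$spec
  for (k in seq_along(spec$indicators)) {
    v <- g$data[[spec$indicators[k]]]
    expect_true(all(v >= spec$scale_min[k] & v <= spec$scale_max[k]))
    expect_true(all(v == round(v)))
  }
})

test_that("invalid scenarios are rejected before any draw", {
  spec <- tiny_spec()
  expect_error(synthetic_scenario(n = 10, spec = spec,
                                  Phi = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(synthetic_scenario(n = 10, spec = spec,
                                  loadings = c(2, 0.8, 1, 1.2, 1, 0.7)),
               "must equal 1")
  expect_error(synthetic_scenario(n = 10, spec = spec,
                                  measurement_error_sd = -1), "positive")
  # kappa too large to keep the scale factor positive
  sc_bad <- tiny_scenario(n = 2000, seed = 1, kappa = c(5, 0))
  expect_error(generate_survey(sc_bad), "positive")
})

test_that("composite descriptives reproduce by-hand values", {
  spec <- tiny_spec()
  # one subject: factor f1 has items y3 = 2, y4 = 4 -> composite 3.0
  row <- data.frame(y1 = 1, y2 = 1, y3 = 2, y4 = 4, y5 = 1, y6 = 1, d1 = 3)
  dat <- rbind(row, row + 1)
  desc <- composite_descriptives(dat, spec)
  expect_equal(desc$summary$mean[desc$summary$factor == "f1"], 3.5)
  expect_equal(diag(desc$correlations), c(eta = 1, f1 = 1, f2 = 1))
  # composites of independently generated factors are near-uncorrelated
  sc <- tiny_scenario(n = 5000, seed = 31)
  sc$Phi <- diag(c(0.6, 0.5)); sc$gamma <- c(0, 0)
  g <- generate_survey(sc)
  desc2 <- composite_descriptives(g$data, spec)
  expect_lt(abs(desc2$correlations["f1", "f2"]), 0.05)
  # a zero-variance composite yields NA correlations, not an error
  dat0 <- dat; dat0$y3 <- 3; dat0$y4 <- 3
  desc0 <- composite_descriptives(dat0, spec)
  expect_true(is.na(desc0$correlations["f1", "f2"]))
})
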