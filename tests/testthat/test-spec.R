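test_that("survey template has the expected identification structure", {
  spec <- lss_template()
  expect_length(spec$indicators, 20)
  expect_length(spec$factor_names, 6)
  expect_length(spec$covariates, 3)
  expect_length(spec$fixed_loadings, 6)       # one pinned loading per factor
  expect_length(free_loadings(spec), 14)      # the estimated loadings
  expect_equal(spec$quantile_grid, c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95))
  # endogenous factor measured by happiness + life satisfaction
  expect_equal(spec$indicators[spec$factor_map == 1],
               c("happiness", "life_satisfaction"))
  # 0-10 scale for the life satisfaction item, 1-5 elsewhere
  expect_equal(spec$scale_max[2], 10)
  expect_true(all(spec$scale_max[-2] == 5))
})

test_that("specification invariants are enforced", {
  # a factor with no fixed loading is unidentified
  expect_error(model_spec(paste0("y", 1:4), c(1, 1, 2, 2), c("eta", "f1"),
                          fixed_loadings = c(1L, 2L)),
               "identification")
  # quantile levels must be interior
  expect_error(model_spec(paste0("y", 1:4), c(1, 1, 2, 2), c("eta", "f1"),
                          quantile_grid = c(0.5, 1.0)),
               "open interval")
  expect_error(model_spec(paste0("y", 1:4), c(1, 1, 2, 7), c("eta", "f1")),
               "no declared factor")
  expect_error(model_spec(paste0("y", 1:4), c(1, 1, 1, 1), c("eta", "f1")),
               "no indicators")
  # grid must increase
  expect_error(model_spec(paste0("y", 1:4), c(1, 1, 2, 2), c("eta", "f1"),
                          quantile_grid = c(0.5, 0.25)),
               "increasing")
})

test_that("prior invariants are enforced", {
  spec <- tiny_spec()
  expect_error(validate_spec(spec, prior_spec(wishart_df = 1)),
               "wishart_df")
  expect_error(validate_spec(spec, prior_spec(error_var_rate = -2)),
               "positive")
  bad <- prior_spec(wishart_scale = matrix(c(1, 2, 2, 1), 2))  # not PD
  expect_error(validate_spec(spec, bad), "positive definite")
  expect_silent(validate_spec(spec, prior_spec()))
})

test_that("bundled template config matches the in-code template", {
  path <- system.file("extdata", "lss2020_config.yaml", package = "bqsem")
  cfg <- read_model_config(path)
  ref <- lss_template()
  expect_equal(cfg$spec$indicators, ref$indicators)
  expect_equal(cfg$spec$factor_map, ref$factor_map)
  expect_equal(cfg$spec$fixed_loadings, ref$fixed_loadings)
  expect_equal(cfg$priors, prior_spec(), ignore_attr = TRUE)
})

test_that("model + prior configuration round-trips through YAML", {
  spec <- lss_template(quantile_grid = c(0.1, 0.5, 0.9))
  priors <- prior_spec(wishart_df = 8, coef_prior_variance = 100)
  path <- tempfile(fileext = ".yaml")
  write_model_config(spec, priors, path)
  back <- read_model_config(path)
  expect_equal(back$spec$indicators, spec$indicators)
  expect_equal(back$spec$factor_map, spec$factor_map)
  expect_equal(back$spec$quantile_grid, spec$quantile_grid)
  expect_equal(back$priors$wishart_df, 8)
  expect_equal(back$priors$coef_prior_variance, 100)
  unlink(path)
})
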