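#!/usr/bin/env Rscript
# Stage 4: does the quantile machinery recover known quantile-varying
# effects?  Fits the quantile SEM at levels 0.1 and 0.9 on the
# location-scale dataset (heteroscedastic structural error on the work-life
# and relationships factors) and compares the estimated slope spread
# slope(0.9) - slope(0.1) against the closed-form truth
# kappa_j * (qnorm(0.9) - qnorm(0.1)).

suppressPackageStartupMessages(library(bqsem))
spec <- lss_template()
sc <- location_scale_scenario(n = 2000, seed = 2021)
# generation is a pure function of the scenario, so this reproduces the
# stage-1 CSV exactly (that file keeps continuous indicators, which the
# ordinal-bounds CSV validator would refuse)
dat <- generate_survey(sc)$data

lo <- fit_bqsem(dat, spec, 0.1, mcmc = mcmc_control(3000, 500, seed = 1,
                                                    score_keep = 0))
hi <- fit_bqsem(dat, spec, 0.9, mcmc = mcmc_control(3000, 500, seed = 2,
                                                    score_keep = 0))
gn <- paste0("gamma", 1:5)
d_est <- colMeans(hi$draws[, gn]) - colMeans(lo$draws[, gn])
d_true <- (true_quantile_coefficients(sc, 0.9) -
             true_quantile_coefficients(sc, 0.1))[gn]
out <- data.frame(factor = spec$factor_names[-1],
                  kappa = sc$kappa,
                  spread_true = round(d_true, 3),
                  spread_est = round(d_est, 3))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.csv(out, "results/tables/quantile_spread_recovery.csv",
          row.names = FALSE)
print(out)
cat("\nBoth heteroscedastic spreads carry the correct sign:",
    all(sign(d_est[sc$kappa != 0]) == sign(d_true[sc$kappa != 0])), "\n")
cat("Note: spreads attenuate toward zero relative to truth because the\n",
    "latent scores are informed through a homoscedastic working\n",
    "likelihood; see the methods vignette.\n")
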