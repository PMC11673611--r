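#!/usr/bin/env Rscript
# Stage 3: the full estimation pipeline on the homoscedastic survey data --
# mean-based SEM plus quantile SEM at the seven study levels
# (0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95), each a single 10,000-iteration
# Gibbs chain with a 2,000-iteration burn-in.  Emits the side-by-side
# estimates table (loadings, structural coefficients, factor covariances,
# 95% credible intervals, significance flags), the 9 x 7 quantile
# coefficient matrix with per-quantile posterior predictive p-values,
# coefficient-profile plots, and convergence diagnostics.
#
# This is the long stage (~15 minutes at n = 2426); pass --fast to use
# 3,000 iterations / 500 burn-in for a quick look.

suppressPackageStartupMessages(library(bqsem))
fast <- "--fast" %in% commandArgs(trailingOnly = TRUE)
mc <- if (fast) mcmc_control(3000, 500) else mcmc_control(10000, 2000)

spec <- lss_template()
dat <- read_survey_csv("results/data/survey_homoscedastic.csv", spec)
res <- run_pipeline(dat, spec, mcmc = mc, seed = 2026,
                    outdir = "results/pipeline")

cat("\nStructural coefficients across quantiles:\n")
print(res$quantile_coefficients, digits = 3)
cat("\nPer-quantile posterior predictive p-values:\n")
print(round(res$ppp, 3))
cat("\nStationarity of the median-fit structural chains:\n")
print(trace_density_report(res$bqsem[["0.5"]]), digits = 2)
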