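#!/usr/bin/env Rscript
# Stage 5: frequentist calibration of the machinery on scaled-down
# replicates -- (a) credible-interval coverage and point recovery over 20
# homoscedastic replicates at n = 500, (b) posterior predictive p-value
# calibration over 30 replicates at n = 300.  Writes a calibration summary
# table.  These are the same computations the acceptance script reports.

suppressPackageStartupMessages(library(bqsem))
spec <- lss_template()
free <- free_loadings(spec)
nm <- c(sprintf("lambda[%d,%d]", free, spec$factor_map[free]),
        paste0("gamma", 1:5))

errs <- covered <- NULL
for (r in 1:20) {
  sc <- homoscedastic_scenario(n = 500, seed = 400 + r)
  g <- generate_survey(sc)
  fit <- fit_bsem(g$data, spec,
                  mcmc = mcmc_control(3000, 500, seed = r, score_keep = 0))
  s <- summarize_fit(fit)
  truth <- c(sc$loadings[free], sc$gamma)
  idx <- match(nm, s$parameter)
  errs <- cbind(errs, s$mean[idx] - truth)
  covered <- cbind(covered, s$lower[idx] <= truth & truth <= s$upper[idx])
}

ppps <- vapply(1:30, function(r) {
  sc <- homoscedastic_scenario(n = 300, seed = 500 + r)
  g <- generate_survey(sc)
  fit <- fit_bsem(g$data, spec, mcmc = mcmc_control(2000, 500, seed = r))
  compute_ppp(fit)$ppp
}, 0.0)

summary_tab <- data.frame(
  quantity = c("mean_abs_error", "max_abs_error", "ci95_coverage",
               "ppp_median", "ppp_in_(0.05,0.95)_rate"),
  value = round(c(mean(abs(errs)), max(abs(errs)), mean(covered),
                  median(ppps), mean(ppps > 0.05 & ppps < 0.95)), 4))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.csv(summary_tab, "results/tables/calibration_summary.csv",
          row.names = FALSE)
print(summary_tab)
cat("\nPer-parameter coverage (20 replicates):\n")
print(setNames(round(rowMeans(covered), 2), nm))
cat("\nThe largest work-life loadings run ~0.1 low and under-cover at\n",
    "n = 500: the inverse-Wishart scale adds ~15/n to each factor's\n",
    "variance at this sample size (see the methods vignette).\n")
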