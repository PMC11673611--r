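# bqsem — Bayesian quantile structural equation models

`bqsem` estimates how latent life domains (work-life, social-life,
relationship, housing-district and public-service satisfaction) shape the
**whole distribution** of a latent outcome such as subjective well-being,
not just its mean.  It is aimed at survey researchers who model ordinal
satisfaction items with confirmatory factor structures and want
quantile-specific structural effects — e.g., "does work-life satisfaction
matter more for the least happy?".

## The model

A measurement model links p indicators to latent factors
ω = (η, ξ₁, …, ξ_q₂),

    yᵢ = Λωᵢ + εᵢ,   εᵢ ~ N(0, Ψ),   ξᵢ ~ N(0, Φ),

with one loading per factor fixed at 1.  The structural equation targets,
for each quantile level τ, the τ-th conditional quantile of η:

    ηᵢ = b₀τ + bτ′dᵢ + γτ′ξᵢ + δᵢ,   Qτ(δᵢ) = 0,

implemented through the asymmetric Laplace working likelihood in its
normal–exponential mixture form, so the whole model — latent scores,
loadings, error variances, structural coefficients, ALD scale, factor
covariance — is sampled by a single-chain Gibbs sampler with exact
conjugate updates (RcppArmadillo).  Setting the error to Gaussian gives the
conventional mean-based SEM (`fit_bsem()`) with the identical measurement
side, so mean and quantile fits are directly comparable.  Because the kind
of survey microdata this design targets is typically access-restricted, the
package ships a synthetic survey generator whose true quantile coefficients
are known in closed form (location-scale construction), making every claim
testable.

## Worked example

```r
library(bqsem)

spec <- lss_template()                       # 20 indicators, 6 factors, 3 covariates
sc   <- homoscedastic_scenario(n = 800, seed = 7)
g    <- generate_survey(sc)                  # data + ground truth

fit <- fit_bqsem(g$data, spec, tau = 0.25,
                 mcmc = mcmc_control(3000, 500, seed = 1))
summary(fit)[c(15, 19:23), ]
```

```
   parameter         mean       lower      upper significant
15        b0 -0.303567117 -0.35511127 -0.2466727        TRUE
19    gamma1  0.001672989 -0.09311687  0.1119453       FALSE
20    gamma2  0.465172500  0.32059070  0.5943794        TRUE
21    gamma3  0.216965374  0.13200631  0.3052625        TRUE
22    gamma4  0.155846929  0.05152893  0.2482675        TRUE
23    gamma5  0.110065936  0.01893599  0.1935507        TRUE
```

Read: at the lower quartile of well-being, a unit of work-life satisfaction
(γ₂) moves the outcome by ~0.47 with a 95% credible interval well away from
zero, while the housing-district factor (γ₁) is flagged insignificant (its
interval straddles zero) — the same calls the generator's truth (γ₂ = 0.54,
γ₁ ≈ 0) would make.  The intercept −0.30 is the 0.25-quantile of the
structural error for a subject at the centered covariate/factor origin
(truth: qnorm(0.25, sd = 0.5) ≈ −0.34).

The full analysis — descriptives, mean model, seven quantile fits
(τ = 0.05…0.95), coefficient tables with credible intervals and
significance flags, per-quantile posterior predictive p-values, and
coefficient-profile plots with 95% ribbons — is one call:

```r
res <- run_pipeline(g$data, spec, mcmc = mcmc_control(10000, 2000),
                    seed = 2026, outdir = "results/pipeline")
```

The numbered drivers under `analysis/` run the whole study on synthetic
data: `01_simulate.R` (datasets + truth records), `02_descriptives.R`,
`03_fit_models.R` (the pipeline at survey scale), `04_quantile_recovery.R`
(estimated vs analytic quantile-slope spreads), `05_calibration.R`
(coverage and PPP calibration over replicates).  Outputs land under
`results/`.

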