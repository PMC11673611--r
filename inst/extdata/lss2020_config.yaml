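model:
  indicators:
  - happiness
  - life_satisfaction
  - housing
  - district
  - work
  - earning
  - income
  - time
  - colleague
  - social_life
  - personal_time
  - relative
  - friend
  - neighbor
  - health_service
  - public_order
  - judicial
  - education_service
  - ssi
  - transportation
  factor_map:
  - 1
  - 1
  - 2
  - 2
  - 3
  - 3
  - 3
  - 3
  - 3
  - 4
  - 4
  - 5
  - 5
  - 5
  - 6
  - 6
  - 6
  - 6
  - 6
  - 6
  factor_names:
  - swb
  - housing_district
  - work_life
  - social_life_f
  - relationships
  - public_service
  fixed_loadings:
  - 1
  - 3
  - 5
  - 10
  - 12
  - 15
  covariates:
  - health_sat
  - education_sat
  - marriage_sat
  quantile_grid:
  - 0.05
  - 0.1
  - 0.25
  - 0.5
  - 0.75
  - 0.9
  - 0.95
  scale_min:
  - 1.0
  - 0.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  scale_max:
  - 5.0
  - 10.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  include_intercepts: no
priors:
  loading_prior_mean: 1.0
  loading_prior_variance: 10000.0
  error_var_shape: 9.0
  error_var_rate: 4.0
  structural_scale_shape: 9.0
  structural_scale_rate: 4.0
  wishart_df: 6.0
  wishart_scale: 15.0
  coef_prior_mean: 0.0
  coef_prior_variance: 10000.0
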