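# Demo pipeline configuration: 30 individuals x 4 trials, full-length tests
# (1 h exploration/sociability, 2 h activity at 1 Hz). Values omitted here
# fall back to behavtype::default_pipeline_config().
n_individuals: 30
n_trials: 4
prop_wild: 0.5
arena:
  width_px: 500
  height_px: 500
  refuge: [0, 200, 60, 300]
  object_point: [250, 480]
  conspecific_point: [490, 250]
  px_per_cm: 16.7
movement:
  step_mean_px: 20
  turn_mu_rad: 0.0
  turn_kappa: 1.0
  p_enter_refuge: 0.02
  p_exit_refuge: 0.05
  ind_sd_log_step: 0.4
  ind_sd_log_exit: 0.6
mcmc:
  univariate: {n_iter: 13000, burn_in: 3000, thin: 10}
  bivariate: {n_iter: 100000, burn_in: 10000, thin: 100}
syndrome_pairs:
  - [exploration, activity]
  - [exploration, sociability]
report:
  digits: 2
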