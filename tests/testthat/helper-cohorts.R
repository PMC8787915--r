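# Small cohort fixtures built in code.

tiny_cohort <- function(n = 24, seed = 1, volumes = FALSE, shape = c(8, 8, 8)) {
  generate_cohort(cohort_config(n_subjects = n, seed = seed,
                                generate_volumes = volumes,
                                volume_shape = shape))
}

# Deterministic two-class trajectories: no noise, distinct slopes.
noisefree_config <- function(n = 20, seed = 3) {
  cohort_config(
    n_subjects = n, seed = seed, generate_volumes = FALSE,
    trajectory_params = list(
      MD = list(baseline_mean = 28, baseline_sd = 0, slope_mean = -1,
                slope_sd = 0, nonlinearity = 0, noise_sd = 0),
      FD = list(baseline_mean = 28, baseline_sd = 0, slope_mean = -4,
                slope_sd = 0, nonlinearity = 0, noise_sd = 0)))
}
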