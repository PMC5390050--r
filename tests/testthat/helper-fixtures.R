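# shared fixtures for the test suite

# exact straight-line calibration series through the origin
exact_series <- function(slope = 10, levels = c(1, 2, 5)) {
  data.frame(level_ug_per_ml = levels, response = slope * levels)
}

# replicated calibration series with additive Gaussian noise
noisy_series <- function(slope = 10, intercept = 0, levels = c(5, 10, 20, 50),
                         reps = 3, sd = 1) {
  x <- rep(levels, each = reps)
  data.frame(level_ug_per_ml = x,
             response = intercept + slope * x + stats::rnorm(length(x), 0, sd))
}

# a noise-free simulation config (single day/lab)
noisefree_config <- function(seed = 1, ...) {
  sim_config(noise_cv = 0, day_effect_cv = 0, lab_effect_cv = 0,
             n_days = 1, n_labs = 1, seed = seed, ...)
}
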