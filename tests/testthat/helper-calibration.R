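# Calibration records are expensive (a Brownian ensemble each); build each
# configuration once per test run and reuse.
.cal_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cal_cache[[key]])) .cal_cache[[key]] <- builder()
  .cal_cache[[key]]
}

# reference configuration: 180 angles, 64 frequencies, 3000-step walks
full_calibration <- function() {
  cached("full", function() calibrate_convention(n_brownian = 100))
}

# reduced configuration for simulation-heavy experiments
fast_settings <- function() df_settings(n_theta = 60, n_freqs = 48)

fast_calibration <- function() {
  cached("fast", function() {
    calibrate_convention(fast_settings(), n_brownian = 100, seed = 515L)
  })
}

# minimal configuration for the many short sessions of the null-rate study
null_settings <- function() df_settings(n_theta = 36, n_freqs = 32)

null_calibration <- function() {
  cached("null", function() {
    calibrate_convention(null_settings(), n_steps = 600, n_brownian = 100,
                         seed = 616L)
  })
}

# deterministic tic-modulated spectral curve for one event series
session_curve <- function(events, duration_s = 300, settings = df_settings()) {
  flags <- bin_events(events, duration_s, settings$dt_s)
  traj <- simulate_walk(length(flags), dt_s = settings$dt_s, v = settings$v,
                        indicator = flags)
  spectral_density(traj, n_theta = settings$n_theta,
                   n_freqs = settings$n_freqs, decades = settings$decades)
}
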