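# Shared desk-scale fixtures, built once per test run.

# small BOLD study: 8x8x4 grid, 120 volumes
small_config <- function(n = 6L, seed = 5L, ...) {
  generator_config(n_participants = n, seed = seed,
                   grid_shape = c(8L, 8L, 4L), n_volumes = 120L, ...)
}

small_cohort <- function(cfg = small_config()) generate_cohort(cfg)

# a run with no stochastic nuisance: useful for exact GLM checks
clean_config <- function(...) {
  small_config(noise_sd = 0, drift_sd = 0, motion_coupling = 0, ...)
}

# sensor fixture kept light: two bands, 200 Hz, 30 s
sensor_test_config <- function(n = 40L, seed = 21L) {
  generator_config(n_participants = n, seed = seed, sensor_fs = 200,
                   sensor_duration = 30, n_channels = 30L)
}

sensor_test_bands <- list(alpha = c(8, 13), beta = c(13, 30))

# Gaussian pulse train waveform at given beat times (s)
pulse_wave <- function(beat_times_s, fs = 50, duration = NULL,
                       width = 0.04, noise_sd = 0) {
  if (is.null(duration)) duration <- max(beat_times_s) + 1
  tt <- seq(0, duration, by = 1 / fs)
  x <- numeric(length(tt))
  for (b in beat_times_s) {
    sel <- which(abs(tt - b) < 4 * width)
    x[sel] <- x[sel] + exp(-0.5 * ((tt[sel] - b) / width)^2)
  }
  if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
  waveform(x, fs, "pulseox")
}

# ibi_series directly from a vector of IBIs (ms)
ibis_from_values <- function(vals) ibi_series(cumsum(c(0, vals)))
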