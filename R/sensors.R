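# Band-limited noise for the sensor generator. Low bands are synthesized
# at a reduced rate (same repeated-halving schedule as the analysis path)
# and spline-interpolated back to fs, so narrow low-frequency bands stay
# numerically stable at kHz rates; the result is rescaled to the target SD.
sensor_band_noise <- function(n, band, fs, sd_targets) {
  fs_gen <- fs; halvings <- 0L
  while (fs_gen > 2.5 && fs_gen / band[2] > 50) {
    fs_gen <- fs_gen / 2; halvings <- halvings + 1L
  }
  n_gen <- if (halvings > 0L) ceiling(n / 2^halvings) + 8L else n
  w <- matrix(stats::rnorm(n_gen * length(sd_targets)), n_gen)
  y <- bandpass(w, band, fs_gen)
  # calibrate against one further analysis-filter pass, pre-interpolation
  s <- apply(bandpass(y, band, fs_gen), 2, stats::sd)
  s[s < .Machine$double.eps] <- 1
  if (halvings > 0L) {
    tg <- seq(0, by = 1 / fs_gen, length.out = n_gen)
    tf <- seq(0, by = 1 / fs, length.out = n)
    y <- apply(y, 2, function(col) stats::spline(tg, col, xout = tf)$y)
  }
  sweep(y, 2, sd_targets / s, "*")
}

#' Simulate a multichannel sensor run for one participant
#'
#' Every channel is a sum over the six standard bands of band-limited
#' Gaussian noise. The target SD of band b is
#' `base_sd * max(0.05, N + slope_b * (age - age_mid))`, so the latent
#' neural amplitude and the band-specific age slopes drive band
#' variability. On top of this, two fixed channel patterns (disjoint
#' channel groups) modulate the alpha-band SD with participant-specific
#' factors — the planted two-component loading structure that ICA should
#' recover from the cohort's alpha band-SD matrix.
#'
#' @param participant one row of a [generate_cohort()] table.
#' @param config an [generator_config()]; `sensor_fs` must exceed twice
#'   the top band edge (160 Hz).
#' @param bands named list of bands (default [default_bands()]); bands at
#'   or above Nyquist are an error.
#' @return A [sensor_run()]; `$truth` holds per-band target SDs, the two
#'   planted channel patterns and the participant's pattern factors.
#' @export
simulate_sensors <- function(participant, config, bands = default_bands()) {
  stopifnot(inherits(config, "rsfa_config"), nrow(participant) == 1L)
  fs <- config$sensor_fs
  top <- max(vapply(bands, `[`, numeric(1), 2L))
  if (fs <= 2 * top) {
    stop(sprintf("aliasing error: sensor_fs %g Hz cannot carry a %g Hz band",
                 fs, top))
  }
  nc <- config$n_channels
  n <- round(config$sensor_duration * fs)
  pid <- as.integer(sub("sub-", "", participant$participant_id))
  set.seed(derive_seed(config$seed, 400000L + pid))
  age_mid <- mean(config$age_range)
  N <- participant$N
  pat <- sensor_patterns(nc)
  g1 <- N - 1
  g2 <- stats::rnorm(1, 0, 0.3)   # second latent pattern factor
  X <- matrix(0, n, nc)
  target <- matrix(0, length(bands), nc,
                   dimnames = list(names(bands), NULL))
  for (bn in names(bands)) {
    slope <- if (bn %in% names(config$age_slope_N_by_band)) {
      config$age_slope_N_by_band[[bn]]
    } else 0
    base <- max(0.05, N + slope * (participant$age - age_mid))
    gain <- rep(base, nc)
    if (bn == "alpha") {
      # the two planted channel patterns are the only participant-varying
      # alpha structure, so the cohort's alpha band-SD matrix is rank-2
      # about its mean and ICA can identify both patterns
      gain <- pmax(0.05, 1 + pat[, 1] * g1 + pat[, 2] * g2)
    }
    target[bn, ] <- gain
    X <- X + sensor_band_noise(n, bands[[bn]], fs, gain)
  }
  sensor_run(t(X), fs,
             truth = list(target_sd = target, patterns = pat,
                          factors = c(g1 = g1, g2 = g2), N = N))
}

# Two fixed, disjoint, focal channel patterns used by the generator:
# exponentially decaying weights anchored at opposite ends of the array.
# The heavy-tailed (focal) profile makes each pattern strongly
# super-Gaussian across channels, which is what ICA needs to identify it.
sensor_patterns <- function(nc) {
  third <- max(2L, nc %/% 3L)
  w1 <- numeric(nc); w2 <- numeric(nc)
  w1[seq_len(third)] <- exp(-(seq_len(third) - 1) / 1.5)
  w2[nc - seq_len(third) + 1L] <- exp(-(seq_len(third) - 1) / 1.5)
  cbind(w1 = 0.5 * w1, w2 = 0.5 * w2)
}
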