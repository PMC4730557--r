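#' Simulate a pulse waveform with LF/HF-modulated heartbeats
#'
#' Beat-to-beat intervals follow a base interval set by the participant's
#' latent vascular gain V (via target heart rate
#' `hr_base - hr_slope_V * (V - 1)` bpm), modulated by sinusoids at 0.10 Hz
#' (LF band) and 0.25 Hz (HF band) whose amplitudes scale with V. A
#' configured fraction of beats is displaced by +/- 40% of the local
#' interval, emulating ectopic beats, and the waveform renders each beat
#' as a Gaussian pulse sampled at the pulse-oximeter rate.
#'
#' @param participant one row of a [generate_cohort()] table.
#' @param config an [generator_config()] object; `physio_duration` must be
#'   at least 120 s and the summed modulation amplitude must stay below the
#'   base interval.
#' @return A [waveform()]; `$truth` holds clean and displaced beat times
#'   (ms) and the indices of displaced beats.
#' @export
simulate_physio <- function(participant, config) {
  stopifnot(inherits(config, "rsfa_config"), nrow(participant) == 1L)
  if (config$physio_duration < 120) {
    stop("physio_duration must be at least 120 s")
  }
  V <- participant$V
  hr <- config$hr_base - config$hr_slope_V * (V - 1)
  base_ibi <- 60000 / hr                       # ms
  amp_lf <- config$lf_amp * V
  amp_hf <- config$hf_amp * V
  if (amp_lf + amp_hf >= base_ibi) {
    stop("invalid config: modulation amplitude reaches the base interval")
  }
  pid <- as.integer(sub("sub-", "", participant$participant_id))
  set.seed(derive_seed(config$seed, 300000L + pid))
  dur_ms <- config$physio_duration * 1000
  beats <- numeric(ceiling(dur_ms / base_ibi) + 16L)
  tcur <- 500; i <- 0L
  while (tcur < dur_ms) {
    i <- i + 1L
    beats[i] <- tcur
    ts <- tcur / 1000
    ibi <- base_ibi + amp_lf * sin(2 * pi * 0.10 * ts) +
      amp_hf * sin(2 * pi * 0.25 * ts + pi / 3)
    tcur <- tcur + ibi
  }
  beats <- beats[seq_len(i)]
  true_beats <- beats
  n_out <- round(config$ibi_outlier_rate * length(beats))
  displaced <- integer()
  if (n_out > 0L) {
    displaced <- sort(sample(2:(length(beats) - 1L), n_out))
    local_ibi <- beats[displaced] - beats[displaced - 1L]
    beats[displaced] <- beats[displaced] +
      sample(c(-1, 1), n_out, replace = TRUE) * 0.4 * local_ibi
    beats <- sort(beats)
  }
  tt <- seq(0, config$physio_duration, by = 1 / config$physio_fs)
  x <- numeric(length(tt))
  width <- 0.04                                # Gaussian pulse SD, s
  for (b in beats / 1000) {
    sel <- which(abs(tt - b) < 4 * width)
    x[sel] <- x[sel] + exp(-0.5 * ((tt[sel] - b) / width)^2)
  }
  waveform(x, config$physio_fs, "pulseox",
           truth = list(beat_times_clean = true_beats,
                        beat_times = beats,
                        displaced = displaced,
                        base_ibi = base_ibi, hr = hr))
}
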