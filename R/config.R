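#' Configuration for the synthetic-cohort generator
#'
#' Bundles every knob of the synthetic study: cohort size and age range,
#' the age slopes of the latent vascular gain (V) and neural amplitude (N),
#' the planted mediation path coefficients, the BOLD grid and acquisition
#' parameters, and the physiological / sensor sampling rates. Defaults
#' emulate a population-based adult lifespan cohort (ages 18-88, roughly
#' uniform across deciles) scanned with a ~2 s TR EPI sequence, 50 Hz pulse
#' oximetry and a 1 kHz multichannel sensor array.
#'
#' @param n_participants cohort size (default 335).
#' @param seed integer seed; every generator output is a pure function of
#'   the config (including this seed) and the participant index.
#' @param age_range years, `c(lo, hi)`; ages are drawn uniformly.
#' @param age_slope_V per-year change of the latent vascular gain V.
#' @param sd_V SD of the Gaussian noise on V.
#' @param age_slope_N per-year change of the latent neural amplitude N.
#' @param sd_N SD of the Gaussian noise on N.
#' @param age_slope_N_by_band named per-band multipliers applied to the
#'   sensor band SDs as an additional linear age effect (per year).
#' @param path_coeffs standardized `(a, b, cprime)` used when generating
#'   mediation triples with a known indirect effect.
#' @param grid_shape BOLD grid dimensions `c(x, y, z)`.
#' @param n_volumes volumes per BOLD run.
#' @param tr repetition time, seconds.
#' @param band resting fluctuation band, Hz.
#' @param fluct_sd baseline SD of the resting band-limited fluctuation at
#'   V = 1 (signal units).
#' @param neural_rest_weight weight of the neural latent in the resting
#'   fluctuation amplitude of neural-labelled voxels; the resting amplitude
#'   there is `fluct_sd * V * (1 + neural_rest_weight * (N - 1))`. Kept
#'   well below 1: resting fluctuations are vascular-dominated.
#' @param noise_sd white measurement noise SD in BOLD runs.
#' @param drift_sd scale of per-voxel linear/quadratic drift coefficients.
#' @param motion_coupling amplitude of the motion-coupled BOLD component.
#' @param task_amplitude task response scale; the true unscaled effect at a
#'   responsive voxel is `task_amplitude * N * V` (vascular-only voxels use
#'   N fixed at 1).
#' @param hr_base,hr_slope_V mean heart rate (bpm) model:
#'   `hr = hr_base - hr_slope_V * (V - 1)` (better vascular function, lower
#'   resting HR).
#' @param lf_amp,hf_amp IBI modulation amplitudes (ms) at V = 1 in the LF
#'   (0.1 Hz) and HF (0.25 Hz) bands; both scale linearly with V.
#' @param ibi_outlier_rate fraction of beats displaced as ectopic outliers.
#' @param physio_fs pulse-waveform sampling rate, Hz.
#' @param physio_duration waveform length, seconds (>= 120 for HRV).
#' @param sensor_fs sensor sampling rate, Hz (must exceed twice the top
#'   band edge, 80 Hz).
#' @param sensor_duration sensor record length, seconds.
#' @param n_channels number of sensor channels.
#' @return An object of class `rsfa_config` (a validated list).
#' @seealso [generate_cohort()], [simulate_rest_bold()], [simulate_physio()]
#' @export
generator_config <- function(n_participants = 335L,
                             seed = 1L,
                             age_range = c(18, 88),
                             age_slope_V = -0.01,
                             sd_V = 0.12,
                             age_slope_N = 0.004,
                             sd_N = 0.10,
                             age_slope_N_by_band = c(subdelta = 0.004,
                                                     delta = 0, theta = 0,
                                                     alpha = 0.004,
                                                     beta = 0.003, gamma = 0),
                             path_coeffs = c(a = -0.5, b = 0.3,
                                             cprime = -0.15),
                             grid_shape = c(16L, 16L, 8L),
                             n_volumes = 250L,
                             tr = 1.97,
                             band = c(0.01, 0.08),
                             fluct_sd = 1.0,
                             neural_rest_weight = 0.3,
                             noise_sd = 0.25,
                             drift_sd = 0.5,
                             motion_coupling = 0.3,
                             task_amplitude = 1.0,
                             hr_base = 70,
                             hr_slope_V = 15,
                             lf_amp = 40,
                             hf_amp = 25,
                             ibi_outlier_rate = 0.02,
                             physio_fs = 50,
                             physio_duration = 300,
                             sensor_fs = 1000,
                             sensor_duration = 120,
                             n_channels = 32L) {
  if (!is.numeric(n_participants) || n_participants < 1) {
    stop("invalid config: 'n_participants' must be a positive count")
  }
  if (diff(age_range) <= 0) stop("invalid config: age_range must increase")
  if (fluct_sd < 0) stop("invalid config: 'fluct_sd' must be >= 0")
  for (nm in c("tr", "physio_fs", "physio_duration", "sensor_fs",
               "sensor_duration")) {
    v <- get(nm)
    if (!is.numeric(v) || any(v <= 0)) {
      stop(sprintf("invalid config: '%s' must be positive", nm))
    }
  }
  if (ibi_outlier_rate < 0 || ibi_outlier_rate >= 1) {
    stop("invalid config: 'ibi_outlier_rate' must be in [0, 1)")
  }
  if (length(grid_shape) != 3L || any(grid_shape < 2)) {
    stop("invalid config: 'grid_shape' must be three dims >= 2")
  }
  cfg <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    age_range = age_range, age_slope_V = age_slope_V, sd_V = sd_V,
    age_slope_N = age_slope_N, sd_N = sd_N,
    age_slope_N_by_band = age_slope_N_by_band, path_coeffs = path_coeffs,
    grid_shape = as.integer(grid_shape), n_volumes = as.integer(n_volumes),
    tr = tr, band = band, fluct_sd = fluct_sd,
    neural_rest_weight = neural_rest_weight, noise_sd = noise_sd,
    drift_sd = drift_sd, motion_coupling = motion_coupling,
    task_amplitude = task_amplitude, hr_base = hr_base,
    hr_slope_V = hr_slope_V, lf_amp = lf_amp, hf_amp = hf_amp,
    ibi_outlier_rate = ibi_outlier_rate, physio_fs = physio_fs,
    physio_duration = physio_duration, sensor_fs = sensor_fs,
    sensor_duration = sensor_duration, n_channels = as.integer(n_channels)
  )
  structure(cfg, class = "rsfa_config")
}

#' @export
print.rsfa_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  participants: %d, ages %g-%g, seed %d\n",
              x$n_participants, x$age_range[1], x$age_range[2], x$seed))
  cat(sprintf("  BOLD grid %s, %d volumes, TR %g s, band %g-%g Hz\n",
              paste(x$grid_shape, collapse = "x"), x$n_volumes, x$tr,
              x$band[1], x$band[2]))
  cat(sprintf("  physio %g Hz x %g s; sensors %d ch @ %g Hz x %g s\n",
              x$physio_fs, x$physio_duration, x$n_channels, x$sensor_fs,
              x$sensor_duration))
  invisible(x)
}
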