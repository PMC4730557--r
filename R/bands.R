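#' Standard frequency bands for sensor variability
#'
#' Subdelta through gamma, as used for band-limited neurophysiological
#' variability. The 0.08-1 Hz gap between subdelta and delta is
#' deliberate: the subdelta band mirrors the fMRI fluctuation band.
#'
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
default_bands <- function() {
  list(subdelta = c(0.01, 0.08), delta = c(1, 4), theta = c(4, 8),
       alpha = c(8, 13), beta = c(13, 30), gamma = c(30, 80))
}

#' Construct a sensor run container
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling frequency, Hz.
#' @param channel_ids channel labels.
#' @param truth optional generator ground truth.
#' @return Object of class `sensor_run`.
#' @export
sensor_run <- function(data, fs, channel_ids = NULL, truth = NULL) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("sensor data must have no missing samples")
  if (fs <= 0) stop("fs must be positive")
  if (is.null(channel_ids)) {
    channel_ids <- sprintf("ch%03d", seq_len(nrow(data)))
  }
  structure(list(data = data, fs = fs, channel_ids = channel_ids,
                 truth = truth),
            class = "sensor_run")
}

# Zero-phase low-pass halving decimation, repeated until the band sits
# comfortably inside the (reduced) bandwidth. Keeps narrow low bands
# (e.g. 0.01-0.08 Hz at 1 kHz) numerically well conditioned.
decimate_for_band <- function(x, fs, band_hi, ratio = 50) {
  while (fs > 2.5 && fs / band_hi > ratio) {
    lp <- signal::butter(4, 0.4, type = "low")
    x <- .filtfilt_mat(as.numeric(lp$b), as.numeric(lp$a), x)
    x <- x[seq(1, nrow(x), by = 2L), , drop = FALSE]
    fs <- fs / 2
  }
  list(x = x, fs = fs)
}

#' Per-channel SD of band-passed sensor signal
#'
#' Zero-phase 4th-order Butterworth band-pass, then the SD over samples for
#' each channel. Very low bands relative to the sampling rate are handled
#' by low-pass decimation before the band-pass so the filter stays well
#' conditioned.
#'
#' @param run a [sensor_run()].
#' @param band `c(lo, hi)` Hz, inside `(0, fs/2)`.
#' @return Named numeric vector, one SD per channel (signal units).
#' @export
band_sd <- function(run, band) {
  stopifnot(inherits(run, "sensor_run"))
  check_band(band, run$fs)
  X <- t(run$data)                       # samples x channels
  dec <- decimate_for_band(X, run$fs, band[2])
  y <- bandpass(dec$x, band, dec$fs)
  out <- apply(y, 2, stats::sd)
  names(out) <- run$channel_ids
  out
}

#' Band variability table for a set of sensor runs
#'
#' @param runs list of [sensor_run()]s (one per participant).
#' @param bands named list of `c(lo, hi)` pairs (default [default_bands()]),
#'   restricted to bands below each run's Nyquist.
#' @return list of class `band_variability`: `values`, a named list of
#'   participants x channels matrices (one per band); `bands`.
#' @export
band_variability <- function(runs, bands = default_bands()) {
  vals <- lapply(bands, function(bb) {
    do.call(rbind, lapply(runs, band_sd, band = bb))
  })
  structure(list(values = vals, bands = bands), class = "band_variability")
}

#' Grand mean of band variability across channels
#'
#' @param bv a [band_variability()] object, or a participants x channels
#'   matrix for a single band.
#' @return Named matrix participants x bands (or a vector for a matrix
#'   input): the arithmetic mean over channels.
#' @export
grand_mean_variability <- function(bv) {
  if (is.matrix(bv)) return(rowMeans(bv))
  stopifnot(inherits(bv, "band_variability"))
  sapply(bv$values, rowMeans)
}

#' Flag artifact components by correlation thresholds
#'
#' A component is flagged when its time course correlates strongly with a
#' reference channel (|r| at least 3 times the SD of all such
#' correlations); for references that require topographic confirmation
#' (e.g. eye channels), the component's spatial map must additionally
#' correlate with a template at |r| at least 2 times the SD of all spatial
#' correlations.
#'
#' @param component_timecourses samples x K matrix (K >= 5).
#' @param reference_channels samples x R matrix with column names.
#' @param spatial_maps features x K matrix (needed when
#'   `spatial_required` is non-empty).
#' @param templates features x Ttemplates matrix of reference topographies.
#' @param spatial_required names of reference columns whose temporal hits
#'   need spatial confirmation.
#' @return list of class `artifact_flags`: `flagged` (logical K),
#'   `temporal_corr` (K x R), `spatial_corr` (K x T or NULL),
#'   `temporal_threshold`, `spatial_threshold`.
#' @export
flag_artifact_components <- function(component_timecourses,
                                     reference_channels,
                                     spatial_maps = NULL,
                                     templates = NULL,
                                     spatial_required = character()) {
  tc <- as.matrix(component_timecourses)
  refs <- as.matrix(reference_channels)
  K <- ncol(tc)
  if (K < 5L) stop("need at least 5 components to estimate the threshold")
  if (is.null(colnames(refs))) {
    colnames(refs) <- sprintf("ref%d", seq_len(ncol(refs)))
  }
  tcor <- stats::cor(tc, refs)
  t_thr <- 3 * stats::sd(as.vector(tcor))
  scor <- NULL; s_thr <- NA_real_
  if (length(spatial_required)) {
    if (is.null(spatial_maps) || is.null(templates)) {
      stop("spatial confirmation requested but maps/templates missing")
    }
    scor <- stats::cor(as.matrix(spatial_maps), as.matrix(templates))
    s_thr <- 2 * stats::sd(as.vector(scor))
  }
  flagged <- logical(K)
  for (k in seq_len(K)) {
    hits <- colnames(refs)[abs(tcor[k, ]) >= t_thr]
    for (h in hits) {
      if (h %in% spatial_required) {
        if (any(abs(scor[k, ]) >= s_thr)) flagged[k] <- TRUE
      } else {
        flagged[k] <- TRUE
      }
    }
  }
  structure(list(flagged = flagged, temporal_corr = tcor,
                 spatial_corr = scor, temporal_threshold = t_thr,
                 spatial_threshold = s_thr),
            class = "artifact_flags")
}
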