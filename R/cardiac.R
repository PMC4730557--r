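#' Construct a physiological waveform container
#'
#' @param values amplitude samples.
#' @param fs sampling frequency, Hz.
#' @param modality `"pulseox"` or `"ecg"`.
#' @param truth optional generator ground truth (e.g. true beat times).
#' @return Object of class `waveform`.
#' @export
waveform <- function(values, fs, modality = c("pulseox", "ecg"),
                     truth = NULL) {
  modality <- match.arg(modality)
  if (fs <= 0) stop("fs must be positive")
  structure(list(values = as.numeric(values), fs = fs, modality = modality,
                 truth = truth),
            class = "waveform")
}

#' Detect heartbeats in a pulse or ECG waveform
#'
#' Finds local maxima above an adaptive prominence threshold — half the
#' spread between the 98th percentile and the median of the waveform,
#' above the median — enforcing a refractory period between beats (the
#' larger peak wins). The high percentile keeps the threshold anchored to
#' the beat amplitude even for waveforms that spend most samples near
#' baseline (sparse pulses, ECG R-waves), where lower percentiles sit in
#' the noise floor.
#'
#' @param w a [waveform()].
#' @param refractory_ms minimum beat separation, ms.
#' @return Beat times in ms from record start.
#' @export
detect_beats <- function(w, refractory_ms = 300) {
  stopifnot(inherits(w, "waveform"))
  x <- w$values
  spread <- stats::quantile(x, 0.98, names = FALSE) - stats::median(x)
  if (spread < .Machine$double.eps) stop("detection error: flat waveform")
  thr <- stats::median(x) + 0.5 * spread
  n <- length(x)
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n],
               FALSE) & x > thr
  idx <- which(is_peak)
  if (length(idx) == 0L) stop("detection error: no peaks found")
  ref_samp <- refractory_ms / 1000 * w$fs
  keep <- idx[1]
  for (i in idx[-1]) {
    if (i - keep[length(keep)] >= ref_samp) {
      keep <- c(keep, i)
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  if (length(keep) < 10L) stop("detection error: fewer than 10 beats")
  (keep - 1L) / w$fs * 1000
}

#' Build an interbeat-interval series from beat times
#'
#' @param beat_times strictly increasing beat times, ms.
#' @return Object of class `ibi_series`: `beat_times` (ms), `ibis` (ms;
#'   the interval ending at `beat_times[i+1]`), `removed` (empty
#'   provenance table).
#' @export
ibi_series <- function(beat_times) {
  if (is.unsorted(beat_times, strictly = TRUE)) {
    stop("beat times must be strictly increasing")
  }
  structure(list(beat_times = beat_times, ibis = diff(beat_times),
                 removed = data.frame(index = integer(), value = numeric(),
                                      pass = integer())),
            class = "ibi_series")
}

#' Iterated SD-criterion outlier rejection for interbeat intervals
#'
#' Screens IBIs for ectopic beats and detection errors. The first pass
#' computes the mean and SD after temporarily excluding the single most
#' extreme observation, then removes every value beyond `mean + / - k*SD`.
#' Subsequent passes recompute mean and SD on the full remaining sample and
#' repeat until no value is removed. Removal provenance (index, value,
#' pass) is recorded.
#'
#' @param ibi an [ibi_series()] or a numeric vector of IBIs (ms).
#' @param k SD multiplier (default 3).
#' @return An `ibi_series` with outliers removed and `removed` filled in.
#'   The interval ending at each retained beat is kept aligned with
#'   `beat_times`.
#' @examples
#' s <- reject_outliers_iterative(c(rep(800, 50), 2000))
#' s$removed  # the 2000 ms interval, removed in pass 1
#' @export
reject_outliers_iterative <- function(ibi, k = 3) {
  if (is.numeric(ibi)) {
    vals <- ibi
    times <- cumsum(c(0, vals))
    ibi <- ibi_series(times)
  }
  vals <- ibi$ibis
  if (length(vals) < 10L) stop("need at least 10 IBIs")
  active <- rep(TRUE, length(vals))
  removed <- list()
  pass <- 0L
  repeat {
    pass <- pass + 1L
    cur_idx <- which(active)
    cur <- vals[cur_idx]
    if (length(cur) < 3L) stop("degenerate series: too few IBIs remain")
    if (pass == 1L) {
      extreme <- which.max(abs(cur - mean(cur)))
      ref <- cur[-extreme]
    } else {
      ref <- cur
    }
    mu <- mean(ref); sg <- stats::sd(ref)
    out <- which(cur > mu + k * sg | cur < mu - k * sg)
    if (length(out) == 0L) break
    removed[[pass]] <- data.frame(index = cur_idx[out], value = cur[out],
                                  pass = pass)
    active[cur_idx[out]] <- FALSE
    if (!any(active)) stop("degenerate series: all IBIs removed")
  }
  kept_idx <- which(active)
  structure(list(beat_times = ibi$beat_times[kept_idx + 1L],
                 ibis = vals[kept_idx],
                 removed = if (length(removed)) do.call(rbind, removed)
                           else ibi$removed),
            class = "ibi_series")
}

# End time (ms) of each interval: constructors keep one more beat time
# than intervals; cleaned series keep exactly the end beat of each kept
# interval.
ibi_end_times <- function(ibi) {
  if (length(ibi$beat_times) == length(ibi$ibis) + 1L) {
    ibi$beat_times[-1]
  } else {
    ibi$beat_times
  }
}

#' Mean heart rate from an IBI series
#'
#' Counts intervals terminating inside each 60-s window from record start
#' and averages the per-window counts as beats per minute. A trailing
#' partial window of at least half the window length is kept with its
#' count scaled to a per-minute rate; shorter remainders are discarded.
#'
#' @param ibi an `ibi_series`.
#' @param window window length, seconds.
#' @return Mean heart rate, beats per minute.
#' @export
mean_hr <- function(ibi, window = 60) {
  t_end <- max(ibi$beat_times) / 1000
  if (t_end < window) stop("record shorter than one window")
  ends <- ibi_end_times(ibi) / 1000
  n_full <- floor(t_end / window)
  counts <- sapply(seq_len(n_full), function(i) {
    sum(ends > (i - 1) * window & ends <= i * window)
  })
  rates <- counts * (60 / window)
  rem <- t_end - n_full * window
  if (rem >= window / 2) {
    cnt <- sum(ends > n_full * window & ends <= t_end)
    rates <- c(rates, cnt * 60 / rem)
  }
  mean(rates)
}

#' Heart-rate-variability spectral power in a band
#'
#' Interpolates the IBI tachogram to a uniform 4 Hz grid (cubic spline),
#' removes a linear trend, estimates the PSD by Welch's method (64-s
#' Hann segments, 50% overlap) and integrates over the band. The
#' conventional bands are LF 0.05-0.15 Hz and HF 0.15-0.4 Hz.
#'
#' @param ibi a cleaned `ibi_series` spanning at least 120 s.
#' @param band `c(lo, hi)` Hz; must lie below the 2 Hz tachogram Nyquist.
#' @param resample_fs uniform tachogram rate, Hz.
#' @return Band power in ms^2.
#' @export
hrv_band_power <- function(ibi, band, resample_fs = 4) {
  if (band[2] > resample_fs / 2) {
    stop("band error: band exceeds tachogram Nyquist")
  }
  tt <- ibi_end_times(ibi) / 1000           # interval end times, s
  dur <- max(tt) - min(tt)
  if (dur < 120) stop("record too short for HRV estimation (< 120 s)")
  grid <- seq(min(tt), max(tt), by = 1 / resample_fs)
  tach <- stats::spline(tt, ibi$ibis, xout = grid, method = "fmm")$y
  tach <- stats::resid(stats::lm(tach ~ grid))
  nper <- min(length(tach), as.integer(64 * resample_fs))
  band_power(tach, resample_fs, band, nperseg = nper)
}

#' PCA vascular index from cardiac summary features
#'
#' Correlation-matrix PCA of the three cardiac summaries (mean HR, LF-HRV,
#' HF-HRV). The first principal component serves as a single latent index
#' of vascular health; its sign is fixed so the HF-HRV loading is
#' positive (higher score, better vascular function).
#'
#' @param features participants x 3 table or matrix with columns mean HR,
#'   LF-HRV, HF-HRV (in that order).
#' @return list of class `vascular_index`: `scores` (participants x 3),
#'   `loadings` (3 x 3, unit-norm columns), `variance_fraction`.
#' @export
vascular_pca <- function(features) {
  X <- as.matrix(features)
  if (nrow(X) < 4L) stop("need at least 4 participants")
  if (ncol(X) != 3L) stop("expected 3 columns: mean HR, LF-HRV, HF-HRV")
  if (any(apply(X, 2, stats::sd) < .Machine$double.eps)) {
    stop("degenerate features: constant column")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  flip <- ifelse(pc$rotation[3, ] < 0, -1, 1)
  rot <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  rownames(rot) <- c("mean_hr", "lf_hrv", "hf_hrv")
  structure(list(scores = scores, loadings = rot, variance_fraction = vf),
            class = "vascular_index")
}

#' Cardiac feature extraction for one waveform
#'
#' Convenience wrapper: beat detection, iterated outlier rejection, mean
#' HR and LF/HF-HRV band powers.
#'
#' @param w a [waveform()].
#' @param lf,hf frequency bands, Hz.
#' @return Named numeric: `mean_hr`, `lf_hrv`, `hf_hrv`.
#' @export
cardiac_features <- function(w, lf = c(0.05, 0.15), hf = c(0.15, 0.4)) {
  beats <- detect_beats(w)
  cleaned <- reject_outliers_iterative(ibi_series(beats))
  c(mean_hr = mean_hr(cleaned),
    lf_hrv = hrv_band_power(cleaned, lf),
    hf_hrv = hrv_band_power(cleaned, hf))
}
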