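#' Canonical double-gamma haemodynamic response function
#'
#' The standard two-gamma HRF: a response gamma peaking at 6 s minus an
#' undershoot gamma peaking at 16 s at 1/6 amplitude, normalized to unit
#' peak.
#'
#' @param t time points, seconds (>= 0).
#' @param peak,undershoot gamma shape parameters (time-to-peak, s).
#' @param ratio undershoot-to-peak amplitude ratio.
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h / max(stats::dgamma(seq(0, 32, by = 0.01), shape = peak, rate = 1))
}

#' Build an HRF-convolved task regressor sampled at scan times
#'
#' Events are laid out on a 0.1 s grid as sticks (duration 0) or boxcars,
#' convolved with the canonical HRF, and sampled at acquisition times
#' `0, TR, 2*TR, ...`.
#'
#' @param events an [event_table()] (one condition; filter first if needed).
#' @param n_volumes number of scans.
#' @param tr repetition time, seconds.
#' @param dt microtime resolution, seconds.
#' @return Numeric vector of length `n_volumes`.
#' @export
hrf_regressor <- function(events, n_volumes, tr, dt = 0.1) {
  dur_total <- n_volumes * tr
  ng <- ceiling(dur_total / dt) + 1L
  stick <- numeric(ng)
  for (i in seq_len(nrow(events))) {
    a <- 1L + round(events$onset[i] / dt)
    b <- max(a, a + round(events$duration[i] / dt) - 1L)
    b <- min(b, ng)
    stick[a:b] <- stick[a:b] + 1
  }
  # unit convention: one isolated stick event yields a unit-peak response
  hrf <- canonical_hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(stick, rev(hrf), type = "open")[seq_len(ng)]
  scan_idx <- 1L + round((seq_len(n_volumes) - 1L) * tr / dt)
  conv[pmin(scan_idx, ng)]
}
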