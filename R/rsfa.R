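#' Build the nuisance design for resting-state cleaning
#'
#' Columns: intercept, linear and quadratic trends, mean WM signal, mean
#' CSF signal, the six motion parameters and their first differences
#' (zero-padded at the first sample) — 17 regressors in all. Near-collinear
#' columns (pairwise |r| > 0.999) are pruned with a warning so degenerate
#' synthetic inputs (e.g. constant motion) stay full rank.
#'
#' @param run a [bold_run()].
#' @return list of class `nuisance_design` with `matrix` (t x k) and
#'   `labels`.
#' @export
build_nuisance <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  if (sum(run$wm_mask) == 0L || sum(run$csf_mask) == 0L) {
    stop("missing mask: WM and CSF masks must be non-empty")
  }
  nt <- dim(run$data)[4]
  if (nrow(run$motion) != nt) stop("motion table length does not match run")
  vox <- matrix(run$data, ncol = nt)          # nvox x t
  wm <- colMeans(vox[as.vector(run$wm_mask), , drop = FALSE])
  csf <- colMeans(vox[as.vector(run$csf_mask), , drop = FALSE])
  tt <- seq(-1, 1, length.out = nt)
  dmotion <- rbind(0, diff(run$motion))
  X <- cbind(1, tt, tt^2, wm, csf, run$motion, dmotion)
  labels <- c("intercept", "linear", "quadratic", "wm", "csf",
              paste0("motion", 1:6), paste0("dmotion", 1:6))
  keep <- prune_collinear(X, protect = 1L)
  if (length(keep) < ncol(X)) {
    warning(sprintf("pruned %d near-collinear nuisance column(s): %s",
                    ncol(X) - length(keep),
                    paste(labels[-keep], collapse = ", ")))
  }
  structure(list(matrix = X[, keep, drop = FALSE], labels = labels[keep]),
            class = "nuisance_design")
}

# Keep columns until adding one is near-collinear (|r| > .999 with a kept
# column, or zero variance apart from the protected intercept).
prune_collinear <- function(X, protect = integer(), tol_r = 0.999) {
  keep <- integer()
  for (j in seq_len(ncol(X))) {
    if (j %in% protect) { keep <- c(keep, j); next }
    if (stats::sd(X[, j]) < 1e-12) next
    ok <- TRUE
    for (k in keep) {
      if (stats::sd(X[, k]) < 1e-12) next
      if (abs(stats::cor(X[, j], X[, k])) > tol_r) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, j)
  }
  keep
}

#' Regress out nuisance and band-pass filter
#'
#' OLS-residualizes the series against the nuisance design, then applies
#' the zero-phase Butterworth band-pass. Residualizing first guarantees
#' orthogonality to the design before any filtering.
#'
#' @param series numeric vector (length t) or t x p matrix of series in
#'   columns.
#' @param design a [build_nuisance()] design (or any list with a `matrix`).
#' @param tr repetition time, seconds.
#' @param band `c(lo, hi)` Hz; `hi` must be below Nyquist `1/(2*tr)`.
#' @return Cleaned, filtered series with the same shape as `series`.
#' @export
clean_and_filter <- function(series, design, tr, band = c(0.01, 0.08)) {
  fs <- 1 / tr
  check_band(band, fs)
  X <- design$matrix
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design error: rank-deficient nuisance design")
  vec <- is.null(dim(series))
  Y <- if (vec) matrix(as.numeric(series), ncol = 1L) else as.matrix(series)
  if (nrow(Y) != nrow(X)) stop("series length does not match design")
  res <- qr.resid(qrX, Y)
  out <- bandpass(res, band, fs)
  if (vec) as.numeric(out) else out
}

#' Compute the resting-state fluctuation amplitude (RSFA) map
#'
#' RSFA at a voxel is the SD (n - 1 denominator) over time of the
#' nuisance-cleaned, band-passed (default 0.01-0.08 Hz) resting signal — a
#' proxy for cerebrovascular reactivity. Voxels outside the union of the
#' tissue masks are marked invalid.
#'
#' @param run a [bold_run()] with at least 50 volumes.
#' @param band `c(lo, hi)` Hz.
#' @param design optional [build_nuisance()] design; built from `run` when
#'   omitted.
#' @return list of class `rsfa_map`: `values` (3D, >= 0), `band`, `mask`.
#' @examples
#' cfg <- generator_config(n_participants = 4, grid_shape = c(6, 6, 2),
#'                         n_volumes = 80, seed = 3)
#' coh <- generate_cohort(cfg)
#' run <- simulate_rest_bold(coh[1, ], cfg)
#' map <- compute_rsfa(run)
#' range(map$values[map$mask])
#' @export
compute_rsfa <- function(run, band = c(0.01, 0.08), design = NULL) {
  stopifnot(inherits(run, "bold_run"))
  nt <- dim(run$data)[4]
  if (nt < 50L) stop("insufficient data: need at least 50 volumes")
  if (is.null(design)) design <- build_nuisance(run)
  grid <- dim(run$data)[1:3]
  Y <- t(matrix(run$data, ncol = nt))         # t x nvox
  cleaned <- clean_and_filter(Y, design, run$tr, band)
  vals <- apply(cleaned, 2, stats::sd)
  mask <- run$gm_mask | run$wm_mask | run$csf_mask
  vals[!as.vector(mask)] <- 0
  structure(list(values = array(vals, grid), band = band, mask = mask),
            class = "rsfa_map")
}

#' @export
print.rsfa_map <- function(x, ...) {
  cat(sprintf("RSFA map (%g-%g Hz): %d valid voxels, median %.3g\n",
              x$band[1], x$band[2], sum(x$mask),
              stats::median(x$values[x$mask])))
  invisible(x)
}
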