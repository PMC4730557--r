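#' Construct a BOLD run container
#'
#' A `bold_run` holds a 4D voxel array (x, y, z, t), the repetition time,
#' disjoint tissue masks and a motion-parameter table — everything the
#' fluctuation-amplitude pipeline needs.
#'
#' @param data 4D numeric array, time last.
#' @param tr repetition time, seconds.
#' @param gm_mask,wm_mask,csf_mask 3D logical arrays on the same grid;
#'   pairwise disjoint.
#' @param motion t x 6 data.frame or matrix (3 translations mm, 3 rotations
#'   rad).
#' @param truth optional list of generator ground truth (synthetic runs).
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr, gm_mask, wm_mask, csf_mask, motion,
                     truth = NULL) {
  dims <- dim(data)
  if (length(dims) != 4L) stop("shape error: 'data' must be 4D (x,y,z,t)")
  grid <- dims[1:3]
  for (m in list(gm_mask, wm_mask, csf_mask)) {
    if (!identical(dim(m), as.integer(grid))) {
      stop("shape error: mask grid does not match data grid")
    }
  }
  if (any((gm_mask & wm_mask) | (gm_mask & csf_mask) | (wm_mask & csf_mask))) {
    stop("masks must be pairwise disjoint")
  }
  motion <- as.matrix(motion)
  if (nrow(motion) != dims[4]) {
    stop("shape error: motion table length does not match volume count")
  }
  structure(list(data = data, tr = tr, gm_mask = gm_mask, wm_mask = wm_mask,
                 csf_mask = csf_mask, motion = motion, truth = truth),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD run: %dx%dx%d grid, %d volumes, TR %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  cat(sprintf("  GM %d, WM %d, CSF %d voxels\n", sum(x$gm_mask),
              sum(x$wm_mask), sum(x$csf_mask)))
  invisible(x)
}

#' Tissue / effect-region labelling of the synthetic grid
#'
#' Partitions the grid into slabs along x: one CSF slab, one WM slab, then
#' grey matter split into a vascular-only region (resting and task
#' amplitude driven by V alone), a neural region (amplitude driven by V and
#' N) and a null region (no latent dependence).
#'
#' @param config an [generator_config()] object.
#' @return 3D character array with values `"csf"`, `"wm"`, `"vascular"`,
#'   `"neural"`, `"null"`.
#' @export
region_labels <- function(config) {
  g <- config$grid_shape
  lab <- array("null", dim = g)
  nx <- g[1]
  gm_start <- 3L
  n_gm <- nx - gm_start + 1L
  n_vasc <- max(1L, floor(n_gm / 3))
  n_neur <- max(1L, floor(n_gm / 3))
  lab[1, , ] <- "csf"
  lab[2, , ] <- "wm"
  lab[gm_start:(gm_start + n_vasc - 1L), , ] <- "vascular"
  lab[(gm_start + n_vasc):(gm_start + n_vasc + n_neur - 1L), , ] <- "neural"
  lab
}

# internal: shared scaffolding for rest and task runs
simulate_bold_common <- function(participant, config, stream) {
  lab <- region_labels(config)
  g <- config$grid_shape
  nt <- config$n_volumes
  nvox <- prod(g)
  pid <- as.integer(sub("sub-", "", participant$participant_id))
  set.seed(derive_seed(config$seed, stream * 100000L + pid))
  tt <- seq(-1, 1, length.out = nt)
  drift <- cbind(tt, tt^2 - mean(tt^2))
  drift_coef <- matrix(stats::rnorm(2L * nvox, 0, config$drift_sd), 2L)
  motion <- apply(matrix(stats::rnorm(nt * 6L, 0, 0.01), nt, 6L), 2, cumsum)
  motion_w <- stats::rnorm(nvox, 0, config$motion_coupling)
  shared_nuis <- band_noise(nt, c(0.005, 0.05), 1 / config$tr, c(1, 1),
                            ncol = 2L)
  base <- t(drift_coef) %*% t(drift)         # nvox x nt
  base <- base + outer(motion_w, as.numeric(scale(motion[, 1])))
  wm_mask <- as.vector(lab == "wm"); csf_mask <- as.vector(lab == "csf")
  base[wm_mask, ] <- base[wm_mask, ] +
    matrix(shared_nuis[, 1], sum(wm_mask), nt, byrow = TRUE)
  # CSF shares part of the WM nuisance but keeps its own component
  base[csf_mask, ] <- base[csf_mask, ] +
    matrix(0.6 * shared_nuis[, 1] + 0.8 * shared_nuis[, 2],
           sum(csf_mask), nt, byrow = TRUE)
  base <- base + matrix(stats::rnorm(nvox * nt, 0, config$noise_sd), nvox)
  list(lab = lab, base = base, motion = motion, nt = nt, nvox = nvox,
       pid = pid)
}

#' Simulate a resting-state BOLD run for one participant
#'
#' Each grey-matter voxel carries a band-limited (default 0.01-0.08 Hz)
#' fluctuation whose SD is set by the participant's latent factors:
#' proportional to V in vascular-labelled voxels, to
#' `V * (1 + w * (N - 1))` (w small; vascular-dominated) in neural-labelled
#' voxels, and latent-independent in null voxels. All voxels additionally
#' receive linear/quadratic drift, a motion-coupled component and white
#' noise; WM and CSF voxels share a common low-frequency nuisance signal.
#'
#' @param participant a single row of a [generate_cohort()] table.
#' @param config an [generator_config()] object.
#' @return A [bold_run()]; `$truth` holds the planted per-voxel fluctuation
#'   SD (`target_sd`), region labels and the participant's latents.
#' @export
simulate_rest_bold <- function(participant, config) {
  stopifnot(inherits(config, "rsfa_config"), nrow(participant) == 1L)
  sc <- simulate_bold_common(participant, config, stream = 1L)
  fs <- 1 / config$tr
  labv <- as.vector(sc$lab)
  V <- participant$V; N <- participant$N
  target <- numeric(sc$nvox)
  target[labv == "vascular"] <- config$fluct_sd * V
  target[labv == "neural"] <- config$fluct_sd * V *
    (1 + config$neural_rest_weight * (N - 1))
  target[labv == "null"] <- config$fluct_sd
  gm <- labv %in% c("vascular", "neural", "null")
  fluct <- matrix(0, sc$nvox, sc$nt)
  if (any(gm)) {
    fl <- band_noise(sc$nt, config$band, fs, target[gm], ncol = sum(gm),
                     calibrate = TRUE)
    fluct[gm, ] <- t(fl)
  }
  dat <- array(t(sc$base + fluct), dim = c(sc$nt, config$grid_shape))
  dat <- aperm(dat, c(2, 3, 4, 1))
  bold_run(dat, config$tr,
           gm_mask = array(gm, config$grid_shape),
           wm_mask = array(labv == "wm", config$grid_shape),
           csf_mask = array(labv == "csf", config$grid_shape),
           motion = sc$motion,
           truth = list(V = V, N = N,
                        target_sd = array(target, config$grid_shape),
                        labels = sc$lab))
}

#' Event table for a task run
#'
#' @param onset event onsets, seconds from run start.
#' @param duration event durations, seconds (0 for stick functions).
#' @param condition condition labels (recycled).
#' @return data.frame of class `event_table`.
#' @export
event_table <- function(onset, duration = 0, condition = "task") {
  if (any(onset < 0)) stop("invalid events: onsets must be non-negative")
  if (any(duration < 0)) stop("invalid events: durations must be >= 0")
  out <- data.frame(onset = onset,
                    duration = rep_len(duration, length(onset)),
                    condition = rep_len(condition, length(onset)),
                    stringsAsFactors = FALSE)
  class(out) <- c("event_table", "data.frame")
  out
}

#' Default sparse event train for the synthetic sensorimotor task
#'
#' @param config an [generator_config()] object.
#' @return An [event_table()] of stick events with deterministically
#'   jittered onset asynchronies (6-14 s), so the task regressor is not
#'   collinear with the intercept or drift terms.
#' @export
default_events <- function(config) {
  dur <- config$n_volumes * config$tr
  soa <- rep(c(6, 14, 9, 12, 7, 13, 8, 11), length.out = 1000)
  onsets <- 10 + cumsum(c(0, soa))
  event_table(onset = onsets[onsets < dur - 25])
}

#' Simulate a task BOLD run for one participant
#'
#' The task signal at a responsive voxel is the canonical double-gamma HRF
#' convolved with the event train, with amplitude `task_amplitude * N * V`
#' in neural-labelled voxels and `task_amplitude * V` in vascular-only
#' voxels — so the true unscaled GLM beta is the neurovascular product and
#' the RSFA-scaled beta tracks N alone. Drift, motion coupling and white
#' noise as in [simulate_rest_bold()].
#'
#' @inheritParams simulate_rest_bold
#' @param events an [event_table()]; all events must end before the run does.
#' @return A [bold_run()]; `$truth$amplitude` holds the planted per-voxel
#'   effect size.
#' @export
simulate_task_bold <- function(participant, events, config) {
  stopifnot(inherits(config, "rsfa_config"), nrow(participant) == 1L)
  run_dur <- config$n_volumes * config$tr
  if (any(events$onset + events$duration >= run_dur)) {
    stop("invalid events: event beyond run end")
  }
  sc <- simulate_bold_common(participant, config, stream = 2L)
  labv <- as.vector(sc$lab)
  V <- participant$V; N <- participant$N
  amp <- numeric(sc$nvox)
  amp[labv == "vascular"] <- config$task_amplitude * V
  amp[labv == "neural"] <- config$task_amplitude * N * V
  reg <- hrf_regressor(events, n_volumes = config$n_volumes, tr = config$tr)
  dat_mat <- sc$base + outer(amp, reg)
  dat <- array(t(dat_mat), dim = c(sc$nt, config$grid_shape))
  dat <- aperm(dat, c(2, 3, 4, 1))
  gm <- labv %in% c("vascular", "neural", "null")
  bold_run(dat, config$tr,
           gm_mask = array(gm, config$grid_shape),
           wm_mask = array(labv == "wm", config$grid_shape),
           csf_mask = array(labv == "csf", config$grid_shape),
           motion = sc$motion,
           truth = list(V = V, N = N,
                        amplitude = array(amp, config$grid_shape),
                        labels = sc$lab))
}
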