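#' Fit a canonical-HRF task GLM per voxel
#'
#' Design: intercept, linear drift and one HRF-convolved regressor per
#' condition. Returns the OLS beta (and t) for the requested condition at
#' every voxel.
#'
#' @param run a [bold_run()].
#' @param events an [event_table()] with at least 3 events.
#' @param condition which condition's beta to return (default the first).
#' @return list of class `beta_map`: `values` (3D), `t` (3D), `condition`,
#'   `scaled = FALSE`, `mask` (union of tissue masks).
#' @export
fit_task_glm <- function(run, events, condition = NULL) {
  stopifnot(inherits(run, "bold_run"))
  if (nrow(events) < 3L) stop("need at least 3 events")
  nt <- dim(run$data)[4]
  run_dur <- nt * run$tr
  if (any(events$onset >= run_dur)) stop("invalid events: onset beyond run end")
  conds <- unique(events$condition)
  if (is.null(condition)) condition <- conds[1]
  if (!condition %in% conds) stop("unknown condition: ", condition)
  regs <- sapply(conds, function(cc) {
    hrf_regressor(events[events$condition == cc, , drop = FALSE],
                  n_volumes = nt, tr = run$tr)
  })
  tt <- seq(-1, 1, length.out = nt)
  X <- cbind(1, tt, regs)
  if (qr(X)$rank < ncol(X)) stop("design error: rank-deficient task design")
  ci <- 2L + match(condition, conds)
  Y <- t(matrix(run$data, ncol = nt))
  st <- .massuni_t(X, Y, ci)
  grid <- dim(run$data)[1:3]
  mask <- run$gm_mask | run$wm_mask | run$csf_mask
  structure(list(values = array(st[1, ], grid), t = array(st[2, ], grid),
                 condition = condition, scaled = FALSE, mask = mask),
            class = "beta_map")
}

#' Scale task betas by RSFA
#'
#' Divides the task beta at each voxel by the RSFA value at the same voxel,
#' discounting vascular gain so the scaled beta tracks neural response
#' amplitude. Voxels whose RSFA falls below a floor (default the 1st
#' percentile of in-mask RSFA) are removed from the mask rather than
#' divided.
#'
#' @param beta a `beta_map` from [fit_task_glm()].
#' @param rsfa an `rsfa_map` from [compute_rsfa()] on the same grid.
#' @param floor_quantile quantile of in-mask RSFA used as the division
#'   floor.
#' @return A `beta_map` with `scaled = TRUE` and the tightened mask.
#' @export
scale_betas <- function(beta, rsfa, floor_quantile = 0.01) {
  stopifnot(inherits(beta, "beta_map"), inherits(rsfa, "rsfa_map"))
  if (!identical(dim(beta$values), dim(rsfa$values))) {
    stop("shape error: beta and RSFA grids differ")
  }
  mask <- beta$mask & rsfa$mask
  rv <- rsfa$values[mask]
  floor_val <- stats::quantile(rv[rv > 0], floor_quantile, names = FALSE)
  ok <- mask & rsfa$values >= floor_val
  vals <- array(NA_real_, dim = dim(beta$values))
  vals[ok] <- beta$values[ok] / rsfa$values[ok]
  structure(list(values = vals, t = NULL, condition = beta$condition,
                 scaled = TRUE, mask = ok),
            class = "beta_map")
}

# Stack a list of beta_maps into participants x voxels over a common mask.
stack_maps <- function(maps) {
  mask <- Reduce(`&`, lapply(maps, `[[`, "mask"))
  Y <- do.call(rbind, lapply(maps, function(m) m$values[mask]))
  list(Y = Y, mask = mask)
}

#' Group-level age regression on beta maps
#'
#' Per-voxel OLS of the participant beta on age, covariates and an
#' intercept; returns the age slope, t and two-sided p maps.
#'
#' @param maps list of `beta_map`s, one per participant (same order as
#'   `cohort`).
#' @param cohort a [generate_cohort()] table (or any data.frame with `age`
#'   and the covariate columns).
#' @param covariates character vector of cohort columns to adjust for.
#' @return list of class `group_stat_map`: `slope`, `t`, `p` (3D arrays),
#'   `df`, `mask`.
#' @export
group_age_regression <- function(maps, cohort, covariates = character()) {
  n <- length(maps)
  if (n != nrow(cohort)) stop("maps and cohort are unpaired")
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov)) {
    stop("missing covariate(s): ", paste(missing_cov, collapse = ", "))
  }
  st <- stack_maps(maps)
  X <- cbind(1, cohort$age)
  for (cv in covariates) X <- cbind(X, cohort[[cv]])
  if (n < ncol(X) + 2L) stop("too few participants for the design")
  res <- .massuni_t(X, st$Y, 2L)
  df <- n - ncol(X)
  grid <- dim(maps[[1]]$values)
  to3d <- function(v) { a <- array(NA_real_, grid); a[st$mask] <- v; a }
  p <- 2 * stats::pt(-abs(res[2, ]), df)
  structure(list(slope = to3d(res[1, ]), t = to3d(res[2, ]), p = to3d(p),
                 df = df, mask = st$mask, correction = "none",
                 threshold_mask = NULL),
            class = "group_stat_map")
}

#' Age regression on scaled-minus-unscaled difference maps
#'
#' Scaled and unscaled maps are on different units (ratio vs raw), so each
#' set is z-scored across participants per voxel before differencing; the
#' age effect on the difference is then tested per voxel with a family-wise
#' correction (permutation max-t by default, or Bonferroni).
#'
#' @param scaled,unscaled lists of `beta_map`s, paired by participant.
#' @param cohort cohort table aligned with the map lists.
#' @param covariates cohort columns to adjust for.
#' @param correction `"maxt"` (permutation of map rows against the design)
#'   or `"bonferroni"`.
#' @param n_perm number of permutations for max-t.
#' @param alpha family-wise level.
#' @param seed RNG seed for the permutations.
#' @return A `group_stat_map` with a `threshold_mask` of voxels surviving
#'   correction.
#' @export
contrast_scaled_unscaled <- function(scaled, unscaled, cohort,
                                     covariates = character(),
                                     correction = c("maxt", "bonferroni"),
                                     n_perm = 1000L, alpha = 0.05,
                                     seed = 1L) {
  correction <- match.arg(correction)
  if (length(scaled) != length(unscaled)) stop("unpaired map lists")
  n <- length(scaled)
  if (n != nrow(cohort)) stop("maps and cohort are unpaired")
  ss <- stack_maps(scaled); us <- stack_maps(unscaled)
  mask <- ss$mask & us$mask
  Ys <- do.call(rbind, lapply(scaled, function(m) m$values[mask]))
  Yu <- do.call(rbind, lapply(unscaled, function(m) m$values[mask]))
  zcol <- function(M) {
    mu <- colMeans(M); sdv <- apply(M, 2, stats::sd)
    sdv[sdv < .Machine$double.eps] <- 1
    sweep(sweep(M, 2, mu), 2, sdv, "/")
  }
  D <- zcol(Ys) - zcol(Yu)
  X <- cbind(1, cohort$age)
  for (cv in covariates) X <- cbind(X, cohort[[cv]])
  res <- .massuni_t(X, D, 2L)
  df <- n - ncol(X)
  tvals <- res[2, ]
  tvals[!is.finite(tvals)] <- 0   # constant-difference voxels carry no effect
  p <- 2 * stats::pt(-abs(tvals), df)
  nvox <- sum(mask)
  if (correction == "bonferroni") {
    surv <- p * nvox < alpha
  } else {
    set.seed(seed)
    maxt <- replicate(n_perm, {
      perm <- sample.int(n)
      tp <- .massuni_t(X, D[perm, , drop = FALSE], 2L)[2, ]
      max(abs(tp[is.finite(tp)]), 0)
    })
    crit <- stats::quantile(maxt, 1 - alpha, names = FALSE)
    if (!is.finite(crit) || crit == 0) crit <- Inf
    surv <- abs(tvals) > crit
  }
  grid <- dim(scaled[[1]]$values)
  to3d <- function(v, fill = NA_real_) {
    a <- array(fill, grid); a[mask] <- v; a
  }
  structure(list(slope = to3d(res[1, ]), t = to3d(tvals), p = to3d(p),
                 df = df, mask = mask, correction = correction,
                 threshold_mask = array(as.vector(to3d(surv, 0)) > 0, grid)),
            class = "group_stat_map")
}
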