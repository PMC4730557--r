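#' Fit three-variable mediation path models
#'
#' All variables (including covariates) are standardized, then three OLS
#' regressions are fit, each including the covariates and an intercept:
#' \describe{
#'   \item{a}{`M ~ IV` — the IV's effect on the mediator.}
#'   \item{c}{`DV ~ IV` — the total effect.}
#'   \item{b, c'}{`DV ~ M + IV` — the mediator's effect controlling for
#'     the IV, and the direct effect.}
#' }
#' The indirect effect is the product `ab = a * b`; with identical
#' covariates across the three fits it equals `c - c'` to numerical
#' precision.
#'
#' @param iv independent variable (e.g. age, years).
#' @param m mediator (e.g. a vascular index score).
#' @param dv dependent variable (e.g. an RSFA component loading).
#' @param covariates optional data.frame/matrix of nuisance covariates
#'   (e.g. gender, handedness), entered in every regression.
#' @return Named numeric: standardized `a`, `b`, `c`, `cprime`, `ab`.
#' @examples
#' d <- simulate_mediation_data(200, -0.5, 0.3, -0.15, seed = 4)
#' fit_paths(d$iv, d$m, d$dv, d[c("gender", "handedness")])
#' @export
fit_paths <- function(iv, m, dv, covariates = NULL) {
  D <- mediation_matrix(iv, m, dv, covariates)
  est <- as.numeric(.fit_paths_mat(D))
  names(est) <- c("a", "b", "c", "cprime", "ab")
  est
}

# Validate, standardize and assemble the [iv, m, dv, covs] matrix.
mediation_matrix <- function(iv, m, dv, covariates = NULL) {
  n <- length(iv)
  if (length(m) != n || length(dv) != n) stop("unequal variable lengths")
  vars <- cbind(iv = iv, m = m, dv = dv)
  if (anyNA(vars)) stop("missing values are not allowed")
  if (any(apply(vars, 2, stats::sd) < .Machine$double.eps)) {
    stop("iv, mediator and dv must be non-constant")
  }
  if (abs(stats::cor(iv, m)) > 0.999) {
    stop("degeneracy error: iv and mediator are collinear")
  }
  D <- zscore_cols(vars)
  if (!is.null(covariates) && NCOL(covariates) > 0L) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != n) stop("covariates not aligned with variables")
    if (anyNA(cv)) stop("missing values are not allowed")
    keep <- apply(cv, 2, stats::sd) > .Machine$double.eps
    if (any(keep)) D <- cbind(D, zscore_cols(cv[, keep, drop = FALSE]))
  }
  if (n < ncol(D) + 2L) stop("too few participants for the model")
  D
}

#' Bias-corrected bootstrap mediation analysis
#'
#' Resamples participants (whole rows: iv, mediator, dv, covariates) with
#' replacement, refits all paths per draw, and forms bias-corrected (BC)
#' percentile confidence intervals: with `z0 = qnorm(` fraction of
#' bootstrap estimates below the point estimate `)`, the CI endpoints are
#' the bootstrap quantiles at `pnorm(2*z0 -/+ qnorm(alpha/2))`.
#' Significance of the indirect path is declared when the CI excludes
#' zero. Defaults follow the convention of 10,000 draws and 99% CIs.
#'
#' @inheritParams fit_paths
#' @param B number of bootstrap draws.
#' @param alpha CI tail mass (0.01 gives a 99% CI).
#' @param seed RNG seed.
#' @param keep_draws keep the B x 5 matrix of bootstrap path estimates in
#'   the result (as `draws`), for diagnostics.
#' @return Object of class `mediation_result`: a `paths` data.frame (rows
#'   a, b, c, cprime, ab; columns beta, se, z, p, ci_lo, ci_hi), plus `B`,
#'   `alpha`, `seed`, `n`, `classification` (mediation / suppression /
#'   none) and `proportion_mediated` (percent).
#' @examples
#' d <- simulate_mediation_data(100, -0.5, 0.3, -0.15, seed = 4)
#' bc_bootstrap_ci(d$iv, d$m, d$dv, B = 200, seed = 1)
#' @export
bc_bootstrap_ci <- function(iv, m, dv, covariates = NULL, B = 10000L,
                            alpha = 0.01, seed = 1L, keep_draws = FALSE) {
  D <- mediation_matrix(iv, m, dv, covariates)
  n <- nrow(D)
  if (n < 20L) stop("need at least 20 participants for the bootstrap")
  est <- as.numeric(.fit_paths_mat(D))
  set.seed(seed)
  bt <- .boot_paths(D, as.integer(B))
  if (bt$discarded > 0.01 * B) {
    stop("more than 1% of bootstrap draws were degenerate")
  }
  boot <- bt$estimates
  path_names <- c("a", "b", "c", "cprime", "ab")
  tab <- data.frame(beta = est, se = NA_real_, z = NA_real_, p = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_,
                    row.names = path_names)
  zc <- stats::qnorm(1 - alpha / 2)
  for (j in seq_along(path_names)) {
    bj <- boot[, j]
    tab$se[j] <- stats::sd(bj)
    tab$z[j] <- est[j] / tab$se[j]
    frac <- mean(bj < est[j])
    frac <- min(max(frac, 1 / (nrow(boot) + 1)), nrow(boot) / (nrow(boot) + 1))
    z0 <- stats::qnorm(frac)
    probs <- stats::pnorm(c(2 * z0 - zc, 2 * z0 + zc))
    ci <- stats::quantile(bj, probs, names = FALSE)
    tab$ci_lo[j] <- ci[1]; tab$ci_hi[j] <- ci[2]
    # smallest conventional level at which the BC CI excludes zero
    tab$p[j] <- bc_alpha_grid(bj, est[j], z0)
  }
  res <- structure(list(paths = tab, B = as.integer(B), alpha = alpha,
                        seed = as.integer(seed), n = n,
                        discarded = bt$discarded,
                        draws = if (keep_draws) {
                          colnames(boot) <- path_names; boot
                        },
                        classification = NA_character_,
                        proportion_mediated = NA_real_),
                   class = "mediation_result")
  res$classification <- classify_effect(res)
  if (abs(tab["c", "beta"]) > .Machine$double.eps) {
    res$proportion_mediated <- proportion_mediated(tab["ab", "beta"],
                                                   tab["c", "beta"])
  }
  res
}

bc_alpha_grid <- function(bj, est, z0, grid = c(0.05, 0.01, 0.001)) {
  for (a in sort(grid)) {
    zc <- stats::qnorm(1 - a / 2)
    ci <- stats::quantile(bj, stats::pnorm(c(2 * z0 - zc, 2 * z0 + zc)),
                          names = FALSE)
    if (ci[1] > 0 || ci[2] < 0) return(a)
  }
  1
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation path model (n = %d, B = %d, %g%% BC bootstrap CI)\n",
              x$n, x$B, 100 * (1 - x$alpha)))
  print(round(x$paths, 4))
  cat(sprintf("classification: %s", x$classification))
  if (is.finite(x$proportion_mediated)) {
    cat(sprintf("; proportion mediated: %d%%",
                round(x$proportion_mediated)))
  }
  cat("\n")
  invisible(x)
}

#' Proportion-mediated effect size
#'
#' The share of the total effect carried by the indirect path,
#' `100 * |ab / c|` percent. Displayed rounded to the nearest integer.
#'
#' @param ab indirect-effect coefficient.
#' @param c total-effect coefficient (non-zero).
#' @return Percent (numeric; not rounded).
#' @examples
#' proportion_mediated(-0.146, -0.305)  # ~48
#' @export
proportion_mediated <- function(ab, c) {
  if (abs(c) < .Machine$double.eps) {
    stop("undefined proportion: total effect c is zero")
  }
  100 * abs(ab / c)
}

#' Classify an indirect effect as mediation, suppression, or none
#'
#' Mediation requires a significant indirect path whose sign matches the
#' total effect with `|c'| < |c|` (controlling the mediator weakens the
#' direct effect); suppression is a significant indirect path with
#' `|c'| > |c|` (controlling the mediator strengthens it).
#'
#' @param result a [bc_bootstrap_ci()] result (or any list with a `paths`
#'   table whose `ab` row has `ci_lo`/`ci_hi`).
#' @return `"mediation"`, `"suppression"` or `"none"`.
#' @export
classify_effect <- function(result) {
  p <- result$paths
  lo <- p["ab", "ci_lo"]; hi <- p["ab", "ci_hi"]
  if (lo <= 0 && hi >= 0) return("none")
  ab <- p["ab", "beta"]; cc <- p["c", "beta"]; cp <- p["cprime", "beta"]
  if (abs(cp) < abs(cc) && sign(ab) == sign(cc)) return("mediation")
  if (abs(cp) > abs(cc)) return("suppression")
  "none"
}

#' One-call mediation analysis on a per-participant table
#'
#' @param data data.frame with one row per participant.
#' @param iv,m,dv column names of the independent variable, mediator and
#'   dependent variable.
#' @param covariates character vector of covariate column names.
#' @param ... passed to [bc_bootstrap_ci()] (`B`, `alpha`, `seed`).
#' @return A `mediation_result`.
#' @export
mediate <- function(data, iv, m, dv,
                    covariates = intersect(c("gender", "handedness"),
                                           names(data)), ...) {
  bc_bootstrap_ci(data[[iv]], data[[m]], data[[dv]],
                  covariates = if (length(covariates)) data[covariates],
                  ...)
}
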