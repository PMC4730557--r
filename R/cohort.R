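#' Generate a synthetic cohort with latent vascular and neural factors
#'
#' Draws ages uniformly over the configured range and builds, per
#' participant, a latent vascular gain `V` and neural amplitude `N` as
#' linear functions of age plus Gaussian noise, truncated at 0.05 so both
#' stay strictly positive (V divides task betas downstream). Gender is a
#' balanced binary indicator and handedness a laterality score in
#' [-100, 100] skewed towards right-handers, both independent of age.
#'
#' @param config an [generator_config()] object.
#' @return A `data.frame` of class `cohort_table` with columns
#'   `participant_id`, `age`, `gender`, `handedness`, `V`, `N`.
#' @examples
#' coh <- generate_cohort(generator_config(n_participants = 50, seed = 7))
#' summary(coh$V)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "rsfa_config"))
  n <- config$n_participants
  if (n < 4L) stop("invalid config: need at least 4 participants")
  set.seed(derive_seed(config$seed, 0L))
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  age_mid <- mean(config$age_range)
  v_intercept <- 1 - config$age_slope_V * age_mid   # V averages ~1 mid-cohort
  n_intercept <- 1 - config$age_slope_N * age_mid
  V <- pmax(0.05, v_intercept + config$age_slope_V * age +
              stats::rnorm(n, 0, config$sd_V))
  N <- pmax(0.05, n_intercept + config$age_slope_N * age +
              stats::rnorm(n, 0, config$sd_N))
  gender <- as.integer(stats::runif(n) < 0.5)
  handedness <- pmin(100, pmax(-100, stats::rnorm(n, 60, 40)))
  out <- data.frame(
    participant_id = sprintf("sub-%04d", seq_len(n)),
    age = age, gender = gender, handedness = handedness, V = V, N = N,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Generate per-participant mediation triples with known path coefficients
#'
#' Builds standardized (iv, mediator, dv) data following the three-variable
#' path model: `m = a*iv + e1`, `dv = b*m + cprime*iv + e2`, with residual
#' variances chosen so every variable has unit population variance. The
#' true indirect effect is `a*b` and the true total effect `c = a*b +
#' cprime`. Covariates (gender, handedness) are generated independently of
#' all three, so adjusted and unadjusted paths coincide in expectation.
#'
#' @param n number of participants.
#' @param a,b,cprime standardized path coefficients; `a^2 <= 1` and
#'   `b^2 + cprime^2 + 2*a*b*cprime <= 1` are required for a valid model.
#' @param seed integer seed.
#' @return data.frame with columns `iv`, `m`, `dv`, `gender`, `handedness`.
#' @examples
#' d <- simulate_mediation_data(335, a = -0.5, b = 0.3, cprime = -0.15,
#'                              seed = 2)
#' fit_paths(d$iv, d$m, d$dv, d[c("gender", "handedness")])
#' @export
simulate_mediation_data <- function(n, a, b, cprime, seed = 1L) {
  var_e1 <- 1 - a^2
  var_dv_explained <- b^2 + cprime^2 + 2 * a * b * cprime
  if (var_e1 < 0 || var_dv_explained > 1) {
    stop("path coefficients imply variance > 1; shrink a, b or cprime")
  }
  set.seed(seed)
  iv <- stats::rnorm(n)
  m <- a * iv + stats::rnorm(n, 0, sqrt(var_e1))
  dv <- b * m + cprime * iv + stats::rnorm(n, 0, sqrt(1 - var_dv_explained))
  data.frame(iv = iv, m = m, dv = dv,
             gender = as.integer(stats::runif(n) < 0.5),
             handedness = stats::rnorm(n, 60, 40))
}
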