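test_that("product and difference forms of the indirect effect agree exactly", {
  set.seed(26)
  for (r in 1:20) {
    n <- sample(30:100, 1)
    covs <- data.frame(gender = rbinom(n, 1, 0.5), handedness = rnorm(n))
    p <- fit_paths(rnorm(n), rnorm(n), rnorm(n), covs)
    expect_lt(abs(p["ab"] - (p["c"] - p["cprime"])), 1e-10)
  }
})

test_that("a pure-chain model is recovered within 3 SE at n = 1000", {
  d <- simulate_mediation_data(1000, a = -0.5, b = 0.4, cprime = 0,
                               seed = 27)
  p <- fit_paths(d$iv, d$m, d$dv, d[c("gender", "handedness")])
  se <- 1 / sqrt(1000)   # rough standardized-coefficient scale
  expect_lt(abs(p["cprime"]), 3 * se)
  expect_lt(abs(p["ab"] - (-0.5 * 0.4)), 3 * se)
  # independent variables: all paths near zero
  set.seed(28)
  p0 <- fit_paths(rnorm(500), rnorm(500), rnorm(500))
  expect_true(all(abs(p0) < 3 / sqrt(500)))
})

test_that("degenerate mediation inputs are refused", {
  x <- rnorm(50)
  expect_error(fit_paths(x, x + 1e-9 * rnorm(50), rnorm(50)), "collinear")
  expect_error(fit_paths(x, rnorm(49), rnorm(50)), "unequal")
  xna <- x; xna[1] <- NA
  expect_error(fit_paths(xna, rnorm(50), rnorm(50)), "missing")
  expect_error(fit_paths(rep(1, 50), rnorm(50), rnorm(50)), "constant")
})

test_that("bootstrap CIs are seeded, standardization-invariant, and match a manual BC computation", {
  d <- simulate_mediation_data(120, -0.5, 0.3, -0.15, seed = 29)
  r1 <- bc_bootstrap_ci(d$iv, d$m, d$dv, B = 500, seed = 4,
                        keep_draws = TRUE)
  r2 <- bc_bootstrap_ci(d$iv, d$m, d$dv, B = 500, seed = 4)
  expect_identical(r1$paths, r2$paths)
  # affine rescaling of the raw variables leaves standardized paths alone
  r3 <- bc_bootstrap_ci(3 * d$iv + 10, -2 * d$m, 0.1 * d$dv + 5,
                        B = 500, seed = 4)
  expect_equal(abs(r3$paths$beta), abs(r1$paths$beta), tolerance = 1e-10)
  # manual bias-corrected endpoints from the stored draws
  bj <- r1$draws[, "ab"]
  est <- r1$paths["ab", "beta"]
  z0 <- qnorm(mean(bj < est))
  zc <- qnorm(1 - r1$alpha / 2)
  manual <- quantile(bj, pnorm(c(2 * z0 - zc, 2 * z0 + zc)), names = FALSE)
  expect_equal(c(r1$paths["ab", "ci_lo"], r1$paths["ab", "ci_hi"]), manual)
  expect_equal(r1$paths["ab", "se"], sd(bj))
})

test_that("the BC interval reduces to the percentile interval for a symmetric bootstrap", {
  d <- simulate_mediation_data(400, 0.5, 0.5, 0, seed = 30)
  r <- bc_bootstrap_ci(d$iv, d$m, d$dv, B = 2000, seed = 6,
                       keep_draws = TRUE)
  bj <- r$draws[, "a"]
  z0 <- qnorm(mean(bj < r$paths["a", "beta"]))
  perc <- quantile(bj, c(r$alpha / 2, 1 - r$alpha / 2), names = FALSE)
  # the median-bias correction is tiny here, so BC ~ percentile
  expect_lt(abs(z0), 0.08)
  expect_equal(r$paths["a", "ci_lo"], perc[1], tolerance = 0.02)
  expect_equal(r$paths["a", "ci_hi"], perc[2], tolerance = 0.02)
})

test_that("proportion mediated reproduces printed worked examples", {
  expect_equal(round(proportion_mediated(-0.146, -0.305)), 48)
  expect_equal(round(proportion_mediated(0.022, -0.308)), 7)
  expect_equal(proportion_mediated(0, -0.3), 0)
  expect_error(proportion_mediated(0.1, 0), "undefined")
})

test_that("effects are classified as mediation, suppression or none", {
  mk <- function(ab, c, cprime, lo, hi) {
    paths <- data.frame(beta = c(0.5, 0.3, c, cprime, ab),
                        se = 0.05, z = 1, p = 0.01,
                        ci_lo = c(-1, -1, -1, -1, lo),
                        ci_hi = c(1, 1, 1, 1, hi),
                        row.names = c("a", "b", "c", "cprime", "ab"))
    list(paths = paths)
  }
  # values printed for the vascular-index model: mediation
  expect_equal(classify_effect(mk(-0.146, -0.305, -0.158, -0.219, -0.080)),
               "mediation")
  # values printed for the alpha-band model: suppression
  expect_equal(classify_effect(mk(0.022, -0.308, -0.330, 0.002, 0.061)),
               "suppression")
  expect_equal(classify_effect(mk(0.02, -0.3, -0.2, -0.01, 0.05)), "none")
})

test_that("mediate() runs end to end on a tidy participant table", {
  d <- simulate_mediation_data(150, -0.5, 0.3, -0.15, seed = 31)
  names(d)[1:3] <- c("age_z", "hrv_pc1", "rsfa_ic1")
  res <- mediate(d, iv = "age_z", m = "hrv_pc1", dv = "rsfa_ic1",
                 B = 500, seed = 8)
  expect_s3_class(res, "mediation_result")
  expect_equal(res$n, 150)
  expect_lt(res$paths["ab", "beta"], 0)
  expect_output(print(res), "classification")
})

test_that("the planted mediation triple is recovered qualitatively end to end", {
  # age -> vascular factor -> RSFA summary, with neural factor carrying
  # an independent positive age effect: Model 1 mediates, Model 2 does not
  cfg <- generator_config(n_participants = 200, seed = 33)
  coh <- generate_cohort(cfg)
  rsfa_summary <- -2 + 2.5 * coh$V + rnorm(200, 0, 0.1)  # vascular-driven
  neural_summary <- coh$N + rnorm(200, 0, 0.05)
  covs <- coh[c("gender", "handedness")]
  m1 <- bc_bootstrap_ci(coh$age, coh$V, rsfa_summary, covs,
                        B = 1000, seed = 9)
  expect_equal(m1$classification, "mediation")
  m3 <- bc_bootstrap_ci(coh$age, coh$V, neural_summary, covs,
                        B = 1000, seed = 10)
  expect_equal(m3$classification, "none")
})
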