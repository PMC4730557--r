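test_that("cohort generation is deterministic and respects configured ranges", {
  cfg <- generator_config(n_participants = 50, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_true(all(a$age >= 18 & a$age <= 88))
  expect_true(all(a$V > 0) && all(a$N > 0))
  expect_equal(nrow(a), 50)
  expect_error(generate_cohort(generator_config(n_participants = 2)),
               "at least 4")
  expect_error(generator_config(n_participants = 0), "positive count")
})

test_that("zero age slope and zero noise give identical latents", {
  cfg <- generator_config(n_participants = 20, seed = 1, age_slope_V = 0,
                          sd_V = 0)
  coh <- generate_cohort(cfg)
  expect_equal(diff(range(coh$V)), 0)
})

test_that("configured V age slope is recovered by OLS within 3 SE", {
  cfg <- generator_config(n_participants = 1000, seed = 42,
                          age_slope_V = -0.01)
  coh <- generate_cohort(cfg)
  fit <- summary(lm(V ~ age, data = coh))$coefficients
  expect_lt(abs(fit["age", "Estimate"] - (-0.01)),
            3 * fit["age", "Std. Error"])
})

test_that("resting runs scale band-limited amplitude with V and are seeded", {
  cfg <- clean_config()
  coh <- small_cohort(cfg)
  p <- coh[1, ]
  run1 <- simulate_rest_bold(p, cfg)
  run2 <- simulate_rest_bold(p, cfg)
  expect_identical(run1$data, run2$data)
  # doubling V doubles the planted fluctuation SD in a vascular voxel
  p2 <- p; p2$V <- 2 * p$V
  run_2v <- simulate_rest_bold(p2, cfg)
  vasc <- run1$truth$labels == "vascular"
  expect_equal(run_2v$truth$target_sd[vasc], 2 * run1$truth$target_sd[vasc])
  v1 <- matrix(run1$data, ncol = 120)[which(as.vector(vasc))[1], ]
  v2 <- matrix(run_2v$data, ncol = 120)[which(as.vector(vasc))[1], ]
  expect_equal(sd(v2) / sd(v1), 2, tolerance = 1e-6)
})

test_that("with all noise sources off a null voxel carries only its fluctuation", {
  cfg <- clean_config(fluct_sd = 0)
  coh <- small_cohort(cfg)
  run <- simulate_rest_bold(coh[1, ], cfg)
  nullvox <- which(as.vector(run$truth$labels == "null"))[1]
  series <- matrix(run$data, ncol = 120)[nullvox, ]
  expect_equal(diff(range(series)), 0)
})

test_that("RSFA recovers the latent vascular gain across a cohort", {
  cfg <- generator_config(n_participants = 40, seed = 9,
                          grid_shape = c(8L, 8L, 4L), n_volumes = 150L)
  coh <- generate_cohort(cfg)
  rs <- vapply(seq_len(40), function(i) {
    run <- simulate_rest_bold(coh[i, ], cfg)
    map <- compute_rsfa(run)
    mean(map$values[run$truth$labels == "vascular"])
  }, numeric(1))
  expect_gt(cor(coh$V, rs), 0.9)
})

test_that("task runs encode the neurovascular product and validate events", {
  cfg <- clean_config()
  coh <- small_cohort(cfg)
  ev <- default_events(cfg)
  run <- simulate_task_bold(coh[1, ], ev, cfg)
  bm <- fit_task_glm(run, ev)
  neur <- run$truth$labels == "neural"
  expect_equal(bm$values[neur], run$truth$amplitude[neur],
               tolerance = 1e-6)
  expect_equal(unique(round(run$truth$amplitude[neur], 10)),
               round(coh$N[1] * coh$V[1], 10))
  late <- event_table(onset = cfg$n_volumes * cfg$tr + 5)
  expect_error(simulate_task_bold(coh[1, ], late, cfg), "beyond run end")
  run2 <- simulate_task_bold(coh[1, ], ev, cfg)
  expect_identical(run$data, run2$data)
})

test_that("physio traces honour the configured beat model", {
  cfg <- small_config(ibi_outlier_rate = 0, lf_amp = 0, hf_amp = 0)
  coh <- small_cohort(cfg)
  w <- simulate_physio(coh[1, ], cfg)
  ibis <- diff(w$truth$beat_times)
  expect_lt(diff(range(ibis)), 1e-9)           # constant IBIs
  expect_equal(mean(ibis), w$truth$base_ibi, tolerance = 1e-9)
  # outlier displacement count matches the configured rate
  cfg2 <- small_config(ibi_outlier_rate = 0.02)
  w2 <- simulate_physio(coh[1, ], cfg2)
  expect_equal(length(w2$truth$displaced),
               round(0.02 * length(w2$truth$beat_times)))
  expect_error(simulate_physio(coh[1, ], small_config(physio_duration = 60)),
               "at least 120")
  expect_error(simulate_physio(coh[1, ], small_config(lf_amp = 2000)),
               "base interval")
})

test_that("LF-only modulation produces LF-dominated HRV downstream", {
  cfg <- small_config(ibi_outlier_rate = 0, hf_amp = 0, lf_amp = 40)
  coh <- small_cohort(cfg)
  w <- simulate_physio(coh[1, ], cfg)
  ibi <- reject_outliers_iterative(ibi_series(w$truth$beat_times))
  lf <- hrv_band_power(ibi, c(0.05, 0.15))
  hf <- hrv_band_power(ibi, c(0.15, 0.4))
  expect_gt(lf / hf, 20)
})

test_that("sensor runs match their per-band SD targets and refuse aliasing", {
  cfg <- sensor_test_config(n = 6L)
  coh <- generate_cohort(cfg)
  run <- simulate_sensors(coh[1, ], cfg, sensor_test_bands)
  est <- band_sd(run, sensor_test_bands$alpha)
  expect_equal(unname(est / run$truth$target_sd["alpha", ]),
               rep(1, 30), tolerance = 0.1)
  low_fs <- generator_config(n_participants = 6, sensor_fs = 100)
  expect_error(simulate_sensors(coh[1, ], low_fs), "aliasing")
  run2 <- simulate_sensors(coh[1, ], cfg, sensor_test_bands)
  expect_identical(run$data, run2$data)
})
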