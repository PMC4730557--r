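test_that("noiseless GLM recovers the true beta to numerical precision", {
  cfg <- clean_config()
  coh <- small_cohort(cfg)
  ev <- default_events(cfg)
  run <- simulate_task_bold(coh[1, ], ev, cfg)
  bm <- fit_task_glm(run, ev)
  gm <- run$truth$labels %in% c("vascular", "neural", "null")
  expect_equal(bm$values[gm], run$truth$amplitude[gm], tolerance = 1e-6)
})

test_that("null runs give calibrated t statistics", {
  # pure-noise null: structured nuisance off, since the task GLM models
  # only an intercept and a linear drift
  cfg <- small_config(task_amplitude = 0, seed = 31, drift_sd = 0,
                      motion_coupling = 0)
  coh <- small_cohort(cfg)
  ev <- default_events(cfg)
  run <- simulate_task_bold(coh[1, ], ev, cfg)
  bm <- fit_task_glm(run, ev)
  gm <- run$truth$labels %in% c("vascular", "neural", "null")
  expect_lt(max(abs(mean(bm$values[gm]))), 0.05)
  expect_gt(mean(abs(bm$t[gm]) < 2), 0.9)
})

test_that("events outside the run and thin designs are refused", {
  cfg <- small_config()
  coh <- small_cohort(cfg)
  late <- event_table(onset = c(10, 20, cfg$n_volumes * cfg$tr + 1))
  run <- simulate_task_bold(coh[1, ], default_events(cfg), cfg)
  expect_error(fit_task_glm(run, late), "beyond run end")
  expect_error(fit_task_glm(run, event_table(onset = c(10, 20))),
               "at least 3")
})

test_that("beta scaling is exact division with a floor", {
  cfg <- small_config()
  run <- simulate_task_bold(small_cohort(cfg)[1, ], default_events(cfg), cfg)
  bm <- fit_task_glm(run, default_events(cfg))
  # RSFA identically 1 reproduces the input
  ones <- structure(list(values = array(1, dim(bm$values)),
                         band = c(0.01, 0.08), mask = bm$mask),
                    class = "rsfa_map")
  sc <- scale_betas(bm, ones)
  expect_equal(sc$values[sc$mask], bm$values[sc$mask])
  expect_true(sc$scaled)
  # RSFA identically c divides all betas by c
  cmap <- ones; cmap$values[] <- 4
  sc4 <- scale_betas(bm, cmap)
  expect_equal(sc4$values[sc4$mask], bm$values[sc4$mask] / 4)
  # zero-RSFA voxels leave the mask instead of being divided
  zmap <- ones
  zmap$values[4, 1, 1] <- 0
  scz <- scale_betas(bm, zmap)
  expect_false(scz$mask[4, 1, 1])
  expect_true(all(is.finite(scz$values[scz$mask])))
  # grid mismatch
  bad <- ones; bad$values <- array(1, c(2, 2, 2)); bad$mask <- array(TRUE, c(2, 2, 2))
  expect_error(scale_betas(bm, bad), "shape")
})

test_that("scaled betas track neural amplitude across participants", {
  cfg <- generator_config(n_participants = 30, seed = 13,
                          grid_shape = c(8L, 8L, 4L), n_volumes = 150L)
  coh <- generate_cohort(cfg)
  ev <- default_events(cfg)
  vals <- t(vapply(seq_len(30), function(i) {
    rest <- simulate_rest_bold(coh[i, ], cfg)
    task <- simulate_task_bold(coh[i, ], ev, cfg)
    map <- compute_rsfa(rest)
    bm <- fit_task_glm(task, ev)
    sc <- scale_betas(bm, map)
    neur <- task$truth$labels == "neural" & sc$mask
    c(unscaled = mean(bm$values[neur]), scaled = mean(sc$values[neur]))
  }, c(unscaled = 0, scaled = 0)))
  expect_gt(cor(vals[, "scaled"], coh$N), 0.9)
  expect_gt(cor(vals[, "unscaled"], coh$N * coh$V), 0.9)
})

test_that("group age regression behaves on exact and permuted inputs", {
  cfg <- small_config(n = 40L, seed = 17)
  coh <- small_cohort(cfg)
  grid <- c(4L, 4L, 2L)
  mask <- array(TRUE, grid)
  mkmap <- function(v) structure(list(values = array(v, grid), t = NULL,
                                      condition = "task", scaled = FALSE,
                                      mask = mask), class = "beta_map")
  # betas exactly equal to age: slope 1, p ~ 0
  maps <- lapply(coh$age, mkmap)
  gs <- group_age_regression(maps, coh)
  expect_equal(unname(gs$slope[1, 1, 1]), 1, tolerance = 1e-10)
  expect_lt(gs$p[1, 1, 1], 1e-12)
  expect_equal(gs$df, 38)
  # permuted ages: about 5% of voxels nominally significant
  set.seed(8)
  nullmaps <- lapply(seq_len(40), function(i) mkmap(rnorm(prod(grid))))
  gn <- group_age_regression(nullmaps, coh)
  expect_lt(mean(gn$p[mask] < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 32))
  expect_error(group_age_regression(maps, coh, covariates = "nope"),
               "missing covariate")
  expect_error(group_age_regression(maps[1:3], coh), "unpaired")
})

test_that("difference contrast is empty for identical inputs and flags planted effects", {
  cfg <- small_config(n = 40L, seed = 19)
  coh <- small_cohort(cfg)
  grid <- c(4L, 4L, 2L)
  mask <- array(TRUE, grid)
  mkmap <- function(v, scaled = FALSE) {
    structure(list(values = array(v, grid), t = NULL, condition = "task",
                   scaled = scaled, mask = mask), class = "beta_map")
  }
  set.seed(9)
  base <- lapply(seq_len(40), function(i) mkmap(rnorm(prod(grid))))
  same <- contrast_scaled_unscaled(base, base, coh, n_perm = 100)
  expect_equal(sum(same$threshold_mask), 0)
  # plant a strong age effect in the scaled set only, voxel (1,1,1)
  scl <- lapply(seq_len(40), function(i) {
    v <- base[[i]]$values
    v[1, 1, 1] <- v[1, 1, 1] + 0.4 * coh$age[i]
    mkmap(v, scaled = TRUE)
  })
  got_perm <- contrast_scaled_unscaled(scl, base, coh, n_perm = 200,
                                       seed = 2)
  got_bonf <- contrast_scaled_unscaled(scl, base, coh,
                                       correction = "bonferroni")
  expect_true(got_perm$threshold_mask[1, 1, 1])
  expect_true(got_bonf$threshold_mask[1, 1, 1])
  expect_lte(sum(got_perm$threshold_mask), 2)
})

test_that("permutation max-t familywise error is controlled under the null", {
  cfg <- small_config(n = 20L)
  grid <- c(3L, 3L, 2L)
  mask <- array(TRUE, grid)
  mkmap <- function(v) structure(list(values = array(v, grid), t = NULL,
                                      condition = "task", scaled = FALSE,
                                      mask = mask), class = "beta_map")
  set.seed(11)
  fw <- vapply(seq_len(120), function(r) {
    coh <- generate_cohort(generator_config(n_participants = 20,
                                            seed = 1000 + r))
    a <- lapply(seq_len(20), function(i) mkmap(rnorm(prod(grid))))
    b <- lapply(seq_len(20), function(i) mkmap(rnorm(prod(grid))))
    res <- contrast_scaled_unscaled(a, b, coh, n_perm = 120, seed = r)
    sum(res$threshold_mask) > 0
  }, logical(1))
  # nominal 0.05 plus Monte-Carlo slack (3 binomial SDs)
  expect_lte(mean(fw), 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
})
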