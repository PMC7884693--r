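test_that("build_grid spaces values evenly and sizes the full grid", {
  g <- build_grid(list(contrast_intensity = c(1.6, 2.2)), 3)
  expect_equal(g$values$contrast_intensity, c(1.6, 1.9, 2.2))

  full <- build_grid(param_ranges(), 3)
  expect_identical(length(full$values), 10L)
  expect_equal(full$total_points, 3^10)

  mid <- build_grid(list(gaussian_mean = c(5, 20)), 1)
  expect_equal(mid$values$gaussian_mean, 12.5)
  expect_error(build_grid(list(a = c(2, 1))), "low <= high")
  expect_error(build_grid(param_ranges(), 0), ">= 1")
})

test_that("manual strategy passes its configuration through untouched", {
  cfg <- degradation_config(gaussian_mean = 6, seed = 1L)
  res <- calibrate(list(), list(), metric = "cwssim", strategy = "manual",
                   manual_config = cfg)
  expect_identical(res$best_config, cfg)
  expect_identical(nrow(res$evaluations), 0L)
  expect_error(calibrate(list(), list(), strategy = "manual"),
               "manual_config")
})

test_that("random strategy draws within ranges and is seed-reproducible", {
  imgs <- lapply(1:2, function(i) make_texture(64, seed = i))
  refs <- lapply(3:4, function(i) make_texture(64, seed = i))
  r1 <- calibrate(imgs, refs, metric = "bhattacharyya", strategy = "random",
                  seed = 5)
  r2 <- calibrate(imgs, refs, metric = "bhattacharyya", strategy = "random",
                  seed = 5)
  expect_identical(r1$best_config, r2$best_config)
  expect_identical(r1$best_objective, r2$best_objective)
  for (p in names(param_ranges())) {
    rng <- param_ranges()[[p]]
    expect_gte(r1$best_config[[p]], rng[1])
    expect_lte(r1$best_config[[p]], rng[2])
  }
})

test_that("similarity calibration recovers a known grid point", {
  ds <- generate_dataset(synthetic_spec(4, side = 64, seed = 21))
  base <- identity_config(seed = 3)
  truth_cfg <- photoreca:::update_config(
    base, list(gaussian_mean = 12.5, gaussian_var = 8))
  tr <- capture_truth(truth_cfg, max_rotation_deg = 2,
                      perspective_jitter = 0.01, seed = 103)
  refs <- lapply(seq_along(ds$images), function(i) {
    simulate_capture(ds$images[[i]], tr, seed = 3000 + i)
  })
  res <- calibrate(ds$images, refs, metric = "bhattacharyya",
                   strategy = "similarity", search = "full_grid",
                   ranges = list(gaussian_mean = c(5, 20)), n_steps = 3,
                   fixed_config = truth_cfg, seed = 3)
  expect_equal(res$best_config$gaussian_mean, 12.5)
  expect_identical(nrow(res$evaluations), 3L)
  expect_equal(res$best_objective, min(res$evaluations$objective))
})

test_that("the similarity strategy beats random draws on average", {
  ds <- generate_dataset(synthetic_spec(3, side = 64, seed = 33))
  base <- identity_config(seed = 1)
  truth_cfg <- photoreca:::update_config(
    base, list(gaussian_mean = 12.5, contrast_intensity = 1.9))
  tr <- capture_truth(truth_cfg, max_rotation_deg = 2,
                      perspective_jitter = 0.01, seed = 7)
  refs <- lapply(seq_along(ds$images), function(i) {
    simulate_capture(ds$images[[i]], tr, seed = 500 + i)
  })
  ranges <- list(gaussian_mean = c(5, 20), contrast_intensity = c(1.6, 2.2))
  sim <- vapply(1:10, function(s) {
    calibrate(ds$images, refs, metric = "bhattacharyya",
              strategy = "similarity", search = "coordinate",
              ranges = ranges, fixed_config = truth_cfg,
              passes = 1, seed = s)$best_objective
  }, numeric(1))
  rnd <- vapply(1:10, function(s) {
    calibrate(ds$images, refs, metric = "bhattacharyya",
              strategy = "random", ranges = ranges,
              fixed_config = truth_cfg, seed = s)$best_objective
  }, numeric(1))
  expect_lte(mean(sim), mean(rnd))
})

test_that("calibration results round-trip through JSON", {
  d <- withr::local_tempdir()
  imgs <- lapply(1:2, function(i) make_texture(64, seed = i))
  res <- calibrate(imgs, imgs, metric = "bhattacharyya",
                   strategy = "similarity", search = "full_grid",
                   ranges = list(gaussian_mean = c(5, 20)), n_steps = 3,
                   fixed_config = identity_config(), seed = 1)
  p <- file.path(d, "cal.json")
  write_calibration(res, p)
  back <- read_calibration(p)
  expect_identical(back$best_config, res$best_config)
  expect_equal(back$best_objective, res$best_objective)
  expect_equal(back$evaluations$objective, res$evaluations$objective)
})

test_that("dual-config selection sits at the least-degrading corner for self-references", {
  imgs <- lapply(1:3, function(i) make_texture(64, seed = i))
  cfgs <- select_dual_configs(
    imgs, imgs, search = "full_grid",
    ranges = list(gaussian_mean = c(5, 20)), n_steps = 3,
    fixed_config = identity_config(), seed = 1)
  expect_identical(length(cfgs), 2L)
  expect_named(cfgs, c("cwssim", "bhattacharyya"))
  # references equal the clean images, so minimal noise maximizes both
  # objectives: the searched dimension collapses to its lowest value
  expect_equal(cfgs$cwssim$gaussian_mean, 5)
  expect_equal(cfgs$bhattacharyya$gaussian_mean, 5)
})
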