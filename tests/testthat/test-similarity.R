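test_that("CW-SSIM satisfies self-similarity, symmetry and bounds", {
  a <- make_texture(64, seed = 1)
  b <- make_texture(64, seed = 2)
  expect_equal(cw_ssim(a, a), 1, tolerance = 1e-9)
  expect_equal(cw_ssim(a, b), cw_ssim(b, a), tolerance = 1e-9)
  s <- cw_ssim(a, b)
  expect_gte(s, -1); expect_lte(s, 1)
  expect_error(cw_ssim(a, make_texture(96)), "mismatch")
  expect_error(cw_ssim(gray_image(matrix(0.5, 32, 32)),
                       gray_image(matrix(0.5, 32, 32))), "64x64")
})

test_that("CW-SSIM is more translation-robust than plain SSIM", {
  a <- make_texture(64, seed = 3)
  shifted <- unclass(a)
  shifted <- rbind(shifted[3:64, ], shifted[1:2, ])  # 2-pixel translate
  b <- gray_image(shifted)
  expect_gte(cw_ssim(a, b), plain_ssim(a, b))
})

test_that("intensity histograms count mass in the right bins", {
  const <- gray_image(matrix(0.42, 16, 16))
  h <- intensity_histogram(const)
  expect_equal(sum(h$bin_counts > 0), 1)
  expect_equal(sum(h$bin_counts), 1, tolerance = 1e-12)

  px <- matrix(0.1, 16, 16); px[5:16, ] <- 0.9
  h2 <- intensity_histogram(gray_image(px))
  expect_equal(sort(h2$bin_counts[h2$bin_counts > 0]), c(0.25, 0.75))

  raw <- intensity_histogram(const, normalize = FALSE)
  expect_equal(sum(raw$bin_counts), 256)
  expect_error(intensity_histogram(const, bins = 1), ">= 2")
})

test_that("Bhattacharyya distance matches its closed form", {
  p <- make_histogram(c(0.5, 0.5))
  expect_equal(bhattacharyya_distance(p, p), 0, tolerance = 1e-7)
  q <- make_histogram(c(0.9, 0.1))
  # sqrt(1 - (sqrt(0.45) + sqrt(0.05)))
  expect_equal(bhattacharyya_distance(p, q), 0.32492, tolerance = 1e-4)
  expect_equal(bhattacharyya_distance(p, q), bhattacharyya_distance(q, p))

  disjoint <- make_histogram(c(1, 0))
  other <- make_histogram(c(0, 1))
  expect_equal(bhattacharyya_distance(disjoint, other), 1)

  un <- structure(list(bin_counts = c(2, 2), normalized = FALSE),
                  class = "intensity_histogram")
  expect_error(bhattacharyya_distance(un, p), "normalized")
  expect_error(bhattacharyya_distance(p, make_histogram(rep(0.25, 4))),
               "equal bin")
})

test_that("compare_sets aggregates per-pair scores in both pairings", {
  imgs <- lapply(1:5, function(i) make_texture(64, seed = i))
  self_rep <- compare_sets(imgs, imgs, pairing = "matched")
  expect_equal(self_rep$mean_cwssim, 1, tolerance = 1e-9)
  expect_equal(self_rep$mean_bhattacharyya, 0, tolerance = 1e-7)
  expect_equal(self_rep$n_pairs, 5L)

  refs <- lapply(6:10, function(i) make_texture(64, seed = i))
  rep <- compare_sets(imgs, refs, pairing = "matched")
  expect_equal(rep$mean_cwssim, mean(rep$per_pair_cwssim), tolerance = 1e-12)
  expect_equal(rep$mean_bhattacharyya, mean(rep$per_pair_bhattacharyya),
               tolerance = 1e-12)
  hand <- vapply(1:5, function(i) cw_ssim(imgs[[i]], refs[[i]]), numeric(1))
  expect_equal(rep$per_pair_cwssim, hand, tolerance = 1e-12)

  # cross pairing scores against the most favourable reference
  cross <- compare_sets(imgs[2], imgs, pairing = "cross")
  expect_equal(cross$per_pair_cwssim, 1, tolerance = 1e-9)
  expect_equal(cross$per_pair_bhattacharyya, 0, tolerance = 1e-7)

  expect_error(compare_sets(list(), imgs), "non-empty")
  expect_error(compare_sets(imgs[1:2], imgs[1:3], pairing = "matched"),
               "equal list lengths")

  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 5L)
  expect_s3_class(glance(rep), "tbl_df")
})

test_that("rising Gaussian noise strictly lowers mean CW-SSIM to the clean image", {
  img <- make_texture(64, seed = 20)
  means <- c(5, 12.5, 20)
  avg <- vapply(means, function(m) {
    cfg <- photoreca:::update_config(
      identity_config(), list(gaussian_mean = m, gaussian_var = 8))
    mean(vapply(1:20, function(s) {
      cw_ssim(img, degrade(img, cfg, seed = s))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(avg) < 0))
})
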