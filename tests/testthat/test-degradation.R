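test_that("Gaussian noise recovers its configured moments on a large image", {
  mid <- gray_image(matrix(0.5, 512, 512))
  expect_identical(add_gaussian_noise(mid, 0, 0), mid)
  set.seed(11)
  out <- add_gaussian_noise(mid, 10, 8)
  delta <- (unclass(out) - unclass(mid)) * 255
  expect_lt(abs(mean(delta) - 10), 0.05)
  expect_lt(abs(stats::var(as.numeric(delta)) - 8), 0.5)
  expect_error(add_gaussian_noise(mid, 0, -1), ">= 0")
  # the printed search-range endpoints are valid configurations
  expect_s3_class(degradation_config(gaussian_mean = 5, gaussian_var = 4),
                  "degradation_config")
  expect_s3_class(degradation_config(gaussian_mean = 20, gaussian_var = 12),
                  "degradation_config")
})

test_that("saturation tint blends toward white or yellowish", {
  rgb <- to_rgb(make_texture(8, seed = 1))
  expect_identical(apply_saturation_shift(rgb, 0, 0.5), rgb)
  expect_error(apply_saturation_shift(make_texture(8), 1, 0.5), "to_rgb")

  set.seed(3)
  out <- apply_saturation_shift(rgb, 1, 1)
  # recover the blend weight from one channel and check the blend formula
  w <- (out[1, 1, 1] - rgb[1, 1, 1]) / (1 - rgb[1, 1, 1])
  expect_gte(w, 0.05); expect_lte(w, 0.25)
  expect_equal(unclass(out), (1 - w) * unclass(rgb) + w, tolerance = 1e-9)

  # white/yellow event ratio ~ Binomial(n, 0.7)
  set.seed(7)
  white <- 0L
  for (i in 1:1000) {
    o <- apply_saturation_shift(rgb, 1, 0.7)
    # the yellowish tint (1, 1, 0.8) pulls blue less than red
    dr <- mean(o[, , 1] - rgb[, , 1]); db <- mean(o[, , 3] - rgb[, , 3])
    white <- white + (abs(dr - db) < 1e-9)
  }
  expect_lt(abs(white / 1000 - 0.7), 0.05)
})

test_that("overexposure applies one truncated-normal global gain", {
  img <- make_texture(16, seed = 2)
  expect_identical(apply_overexposure(img, 1, 0), img)
  g14 <- apply_overexposure(gray_image(matrix(c(0.5, 0.9), 8, 8)), 1.4, 0)
  expect_equal(unclass(g14)[1, 1], 0.7, tolerance = 1e-12)
  expect_equal(unclass(g14)[2, 1], 1.0, tolerance = 1e-12)

  low <- gray_image(matrix(0.2, 8, 8))
  set.seed(5)
  gains <- replicate(2000, unclass(apply_overexposure(low, 1.2, 0.3))[1, 1] / 0.2)
  expect_lt(abs(mean(gains) - 1.2), 0.05)
  expect_error(apply_overexposure(img, 1, -0.1), ">= 0")
})

test_that("contrast correction is the fixed-point affine map", {
  img <- make_texture(16, seed = 3)
  expect_identical(apply_contrast(img, 1), img)
  px <- gray_image(matrix(c(0.5, 0.6), 8, 8))
  out <- apply_contrast(px, 2)
  expect_equal(unclass(out)[1, 1], 0.5, tolerance = 1e-12)
  expect_equal(unclass(out)[2, 1], 0.7, tolerance = 1e-12)
  expect_error(apply_contrast(img, 0), "> 0")
})

test_that("motion blur uses a unit-mass line kernel with reflected borders", {
  img <- make_texture(32, seed = 4)
  expect_identical(apply_motion_blur(img, 0, 5), img)
  const <- gray_image(matrix(0.3, 16, 16))
  set.seed(1)
  expect_lt(max(abs(unclass(apply_motion_blur(const, 1, 5)) - 0.3)), 1e-9)

  for (th in c(0, 0.4, 1.1, 2.5)) {
    expect_equal(sum(photoreca:::motion_kernel(5, th)), 1, tolerance = 1e-12)
  }

  # interior pixels agree with a direct convolution oracle
  set.seed(9)
  out <- apply_motion_blur(img, 1, 5)
  set.seed(9)             # replay the same draws: occurrence, then angle
  stats::runif(1)
  th <- stats::runif(1, 0, pi)
  kk <- photoreca:::motion_kernel(5, th)
  r <- (nrow(kk) %/% 2)
  oracle <- matrix(0, 32, 32)
  for (i in (1 + r):(32 - r)) {
    for (j in (1 + r):(32 - r)) {
      oracle[i, j] <- sum(unclass(img)[(i - r):(i + r), (j - r):(j + r)] * kk)
    }
  }
  inner <- (1 + r):(32 - r)
  expect_lt(max(abs(unclass(out)[inner, inner] - oracle[inner, inner])), 1e-9)
  expect_error(apply_motion_blur(img, 1, 0), ">= 1")
})

test_that("Radon round trip reconstructs a phantom accurately", {
  ph <- make_phantom(128)
  sino <- radon_transform(ph)
  rec <- iradon_fbp(sino, 0:179, 128, 128)
  expect_lt(mean((rec - unclass(ph))^2), 5e-3)
})

test_that("moire blends a filtered back-projection reconstruction", {
  img <- make_texture(64, seed = 5)
  expect_identical(apply_moire(img, 0), img)
  set.seed(2)
  out <- apply_moire(img, 1)
  expect_identical(dim(unclass(out)), dim(unclass(img)))
  expect_gt(mean((unclass(out) - unclass(img))^2), 0)
  expect_error(apply_moire(to_rgb(img), 1), "2-D")
  tall <- gray_image(matrix(0.5, 64, 16))
  expect_error(apply_moire(tall, 1), "aspect")
})

test_that("Poisson shot noise is centred with variance lambda", {
  mid <- gray_image(matrix(0.5, 512, 512))
  expect_identical(add_poisson_noise(mid, 0), mid)
  set.seed(21)
  out <- add_poisson_noise(mid, 10)
  delta <- (unclass(out) - unclass(mid)) * 255
  expect_lt(abs(stats::var(as.numeric(delta)) - 10), 0.5)
  expect_lt(abs(mean(delta) / 255), 0.001)
  expect_error(add_poisson_noise(mid, -2), ">= 0")
})

test_that("JPEG compression round trips and degrades monotonically", {
  img <- make_texture(64, seed = 6)
  set.seed(1)
  lossless <- jpeg_compress(img, c(0, 0))
  psnr <- 10 * log10(1 / mean((unclass(lossless) - unclass(img))^2))
  expect_gt(psnr, 40)

  set.seed(2); lo <- jpeg_compress(img, c(30, 30))
  set.seed(2); hi <- jpeg_compress(img, c(70, 70))
  expect_gte(mean((unclass(hi) - unclass(img))^2),
             mean((unclass(lo) - unclass(img))^2))
  expect_identical(dim(unclass(lo)), dim(unclass(img)))
  expect_error(jpeg_compress(img, c(70, 30)), "low <= high")
})

test_that("the composed pipeline honours identity, determinism and order", {
  img <- make_texture(96, seed = 7)
  expect_identical(unclass(degrade(img, identity_config())), unclass(img))

  cfg <- degradation_config(seed = 42)
  expect_identical(degrade(img, cfg), degrade(img, cfg))
  expect_false(identical(degrade(img, cfg), degrade(img, cfg, seed = 43)))

  out <- degrade(img, cfg)
  expect_identical(dim(unclass(out)), dim(unclass(img)))
  s <- cw_ssim(img, out)
  expect_gt(s, 0); expect_lt(s, 1)

  expect_error(degrade(img, cfg, order = c(1, 1, 2:7)), "permutation")
  # alternative stage order is accepted and still deterministic
  alt <- degrade(img, cfg, order = c(6, 1:5, 7, 8))
  expect_identical(alt, degrade(img, cfg, order = c(6, 1:5, 7, 8)))
})

test_that("configs serialize to JSON and back unchanged", {
  d <- withr::local_tempdir()
  cfg <- degradation_config(gaussian_mean = 7.5, moire_prob = 0.4, seed = 9L)
  p <- file.path(d, "cfg.json")
  write_config(cfg, p)
  expect_equal(read_config(p), cfg)
  expect_error(degradation_config(saturation_prob = 1.5), "\\[0, 1\\]")
  expect_error(degradation_config(compression_rate_range = c(80, 20)),
               "low <= high")
})
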