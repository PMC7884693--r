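#' Degradation pipeline configuration
#'
#' Bundles the ten calibratable hyperparameters of the monitor-to-camera
#' capture simulator together with its fixed settings. Defaults sit at the
#' midpoint of each calibration range; see [param_ranges()] for the ranges
#' themselves.
#'
#' @param gaussian_mean Mean of additive Gaussian noise, on the 0-255
#'   intensity scale (calibration range 5-20).
#' @param gaussian_var Variance of the Gaussian noise, 0-255 scale (4-12).
#' @param saturation_prob Probability that a saturation tint event occurs
#'   (0.5-0.8).
#' @param white_yellow_ratio Fraction of tint events that use the white tint
#'   rather than the yellowish one (0.6-0.8).
#' @param overexposure_mean Mean of the global multiplicative exposure gain
#'   (1-1.4).
#' @param overexposure_var Variance of the exposure gain (0.2-0.4).
#' @param contrast_intensity Contrast correction factor about mid-gray
#'   (1.6-2.2).
#' @param motion_prob Probability of motion blur (0.2-0.5).
#' @param moire_prob Probability of moire interference (0.3-0.9).
#' @param poisson_lambda Shot-noise scaling lambda, 0-255 scale (2-10).
#' @param motion_intensity Motion blur kernel length in pixels; fixed to 5.
#' @param compression_rate_range JPEG compression rate range in percent;
#'   fixed to `c(30, 70)` (quality = 100 - rate).
#' @param apply_compression Whether the JPEG stage runs at all.
#' @param seed RNG seed making the whole pipeline a pure function of
#'   (image, config).
#' @return A `degradation_config` object (a named list).
#' @export
degradation_config <- function(gaussian_mean = 12.5,
                               gaussian_var = 8,
                               saturation_prob = 0.65,
                               white_yellow_ratio = 0.7,
                               overexposure_mean = 1.2,
                               overexposure_var = 0.3,
                               contrast_intensity = 1.9,
                               motion_prob = 0.35,
                               moire_prob = 0.6,
                               poisson_lambda = 6,
                               motion_intensity = 5,
                               compression_rate_range = c(30, 70),
                               apply_compression = TRUE,
                               seed = 0L) {
  cfg <- list(
    gaussian_mean = as.numeric(gaussian_mean),
    gaussian_var = as.numeric(gaussian_var),
    saturation_prob = as.numeric(saturation_prob),
    white_yellow_ratio = as.numeric(white_yellow_ratio),
    overexposure_mean = as.numeric(overexposure_mean),
    overexposure_var = as.numeric(overexposure_var),
    contrast_intensity = as.numeric(contrast_intensity),
    motion_prob = as.numeric(motion_prob),
    moire_prob = as.numeric(moire_prob),
    poisson_lambda = as.numeric(poisson_lambda),
    motion_intensity = as.numeric(motion_intensity),
    compression_rate_range = as.numeric(compression_rate_range),
    apply_compression = isTRUE(apply_compression),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "degradation_config")
}

validate_config <- function(cfg) {
  probs <- c("saturation_prob", "white_yellow_ratio", "motion_prob",
             "moire_prob")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(p, " must lie in [0, 1], got ", cfg[[p]], call. = FALSE)
    }
  }
  for (p in c("gaussian_mean", "gaussian_var", "overexposure_var",
              "poisson_lambda")) {
    if (cfg[[p]] < 0) stop(p, " must be >= 0", call. = FALSE)
  }
  if (cfg$contrast_intensity <= 0) {
    stop("contrast_intensity must be > 0", call. = FALSE)
  }
  if (cfg$motion_intensity < 1) {
    stop("motion_intensity must be >= 1", call. = FALSE)
  }
  rr <- cfg$compression_rate_range
  if (length(rr) != 2L || any(rr < 0) || any(rr > 100) || rr[1] > rr[2]) {
    stop("compression_rate_range must be a low <= high pair within [0, 100]",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Identity configuration
#'
#' A configuration under which [degrade()] is the identity map: all event
#' probabilities zero, zero noise magnitudes, unit gain and contrast, and
#' compression disabled.
#'
#' @param seed RNG seed carried along (irrelevant to the output).
#' @return A `degradation_config`.
#' @export
identity_config <- function(seed = 0L) {
  degradation_config(
    gaussian_mean = 0, gaussian_var = 0, saturation_prob = 0,
    white_yellow_ratio = 0, overexposure_mean = 1, overexposure_var = 0,
    contrast_intensity = 1, motion_prob = 0, moire_prob = 0,
    poisson_lambda = 0, apply_compression = FALSE, seed = seed
  )
}

#' Calibration ranges of the ten hyperparameters
#'
#' @return A named list of `c(low, high)` pairs.
#' @export
param_ranges <- function() {
  list(
    gaussian_mean = c(5, 20),
    gaussian_var = c(4, 12),
    saturation_prob = c(0.5, 0.8),
    white_yellow_ratio = c(0.6, 0.8),
    overexposure_mean = c(1, 1.4),
    overexposure_var = c(0.2, 0.4),
    contrast_intensity = c(1.6, 2.2),
    motion_prob = c(0.2, 0.5),
    moire_prob = c(0.3, 0.9),
    poisson_lambda = c(2, 10)
  )
}

#' Read/write a degradation configuration as JSON
#'
#' @param cfg A `degradation_config`.
#' @param path File path.
#' @return `read_config()` returns a `degradation_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "degradation_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(degradation_config, x)
}

# Deterministic 31-bit hash of a config (seed field included), used to give
# every config its own reproducible stream of operator draws.
config_seed <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 7
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Additive Gaussian noise
#'
#' Adds i.i.d. `Normal(mean, var)` noise per pixel on the 0-255 intensity
#' scale, then clips to the unit interval. Uses R's global RNG.
#'
#' @param img A [gray_image()] or [rgb_image()].
#' @param mean,var Noise mean and variance on the 0-255 scale.
#' @return The same kind of image.
#' @export
add_gaussian_noise <- function(img, mean, var) {
  if (var < 0) stop("`var` must be >= 0", call. = FALSE)
  if (mean == 0 && var == 0) return(img)
  n <- stats::rnorm(length(img), mean = mean, sd = sqrt(var))
  out <- unclass(img) + n / 255
  rewrap(array(out, dim(img) %||% c(nrow(img), ncol(img))), img)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Saturation tint shift
#'
#' With probability `prob` the image is blended toward a tint colour --
#' white `(1, 1, 1)` with probability `white_yellow_ratio`, otherwise a
#' yellowish tint `(1, 1, 0.8)` -- with a blend weight drawn uniformly in
#' `[0.05, 0.25]`. Models the white-balance shift of photographing a
#' monitor under ambient light.
#'
#' @param img An [rgb_image()]; grayscale inputs are rejected (call
#'   [to_rgb()] first).
#' @param prob Event probability.
#' @param white_yellow_ratio Probability a tint event is white.
#' @return An [rgb_image()].
#' @export
apply_saturation_shift <- function(img, prob, white_yellow_ratio) {
  if (!is_rgb(img)) {
    stop("saturation shift needs an rgb_image; convert with to_rgb() first",
         call. = FALSE)
  }
  if (prob < 0 || prob > 1 || white_yellow_ratio < 0 ||
      white_yellow_ratio > 1) {
    stop("`prob` and `white_yellow_ratio` must lie in [0, 1]", call. = FALSE)
  }
  if (prob == 0 || stats::runif(1) >= prob) return(img)
  tint <- if (stats::runif(1) < white_yellow_ratio) c(1, 1, 1) else c(1, 1, 0.8)
  w <- stats::runif(1, 0.05, 0.25)
  out <- unclass(img)
  for (ch in 1:3) out[, , ch] <- (1 - w) * out[, , ch] + w * tint[ch]
  rewrap(out, img)
}

#' Overexposure
#'
#' Draws one global gain `g ~ Normal(gain_mean, gain_var)` per image,
#' truncated at zero, and returns `clip(g * img)`. A single gain models
#' ambient lighting and the camera's auto-exposure.
#'
#' @param img Gray or RGB image.
#' @param gain_mean,gain_var Gain mean and variance.
#' @return The same kind of image.
#' @export
apply_overexposure <- function(img, gain_mean, gain_var) {
  if (gain_var < 0) stop("`gain_var` must be >= 0", call. = FALSE)
  if (gain_mean == 1 && gain_var == 0) return(img)
  g <- max(0, stats::rnorm(1, gain_mean, sqrt(gain_var)))
  rewrap(unclass(img) * g, img)
}

#' Contrast correction
#'
#' `out = clip((in - 0.5) * intensity + 0.5)`, per channel. Mid-gray is a
#' fixed point; `intensity = 1` is the identity.
#'
#' @param img Gray or RGB image.
#' @param intensity Contrast factor (> 0).
#' @return The same kind of image.
#' @export
apply_contrast <- function(img, intensity) {
  if (intensity <= 0) stop("`intensity` must be > 0", call. = FALSE)
  if (intensity == 1) return(img)
  rewrap((unclass(img) - 0.5) * intensity + 0.5, img)
}

# Length-`len` line kernel at angle `theta` (radians), rasterized with
# bilinear weights and normalized to unit mass.
motion_kernel <- function(len, theta) {
  size <- 2L * as.integer(ceiling(len / 2)) + 1L
  k <- matrix(0, size, size)
  c0 <- (size + 1) / 2
  steps <- seq(-(len - 1) / 2, (len - 1) / 2, length.out = max(2L, 4L * len))
  for (s in steps) {
    x <- c0 + s * cos(theta)
    y <- c0 + s * sin(theta)
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    for (dd in list(c(0, 0, (1 - fx) * (1 - fy)), c(0, 1, fx * (1 - fy)),
                    c(1, 0, (1 - fx) * fy), c(1, 1, fx * fy))) {
      yy <- y0 + dd[1]; xx <- x0 + dd[2]
      if (yy >= 1 && yy <= size && xx >= 1 && xx <= size) {
        k[yy, xx] <- k[yy, xx] + dd[3]
      }
    }
  }
  k / sum(k)
}

#' Motion blur
#'
#' With probability `prob`, convolves with a unit-mass line kernel of length
#' `intensity` pixels at an angle drawn uniformly in `[0, 180)` degrees;
#' borders are handled by reflection.
#'
#' @param img Gray or RGB image.
#' @param prob Event probability.
#' @param intensity Kernel length in pixels (>= 1).
#' @return The same kind of image.
#' @export
apply_motion_blur <- function(img, prob, intensity = 5) {
  if (intensity < 1) stop("`intensity` must be >= 1", call. = FALSE)
  if (prob == 0 || stats::runif(1) >= prob) return(img)
  theta <- stats::runif(1, 0, pi)
  k <- motion_kernel(intensity, theta)
  if (is_rgb(img)) {
    out <- unclass(img)
    for (ch in 1:3) out[, , ch] <- cpp_convolve2_reflect(out[, , ch], k)
    return(rewrap(out, img))
  }
  rewrap(cpp_convolve2_reflect(unclass(img), k), img)
}

#' Radon transform and filtered back-projection
#'
#' `radon_transform()` computes line integrals of the image at the given
#' projection angles (unit detector spacing, rays through the padded image
#' support). `iradon_fbp()` reconstructs by Ram-Lak-filtered
#' back-projection. The pair underlies the moire operator: the
#' reconstruction's streak and ring artifacts stand in for the interference
#' fringes a camera sensor picks up from a monitor grid.
#'
#' @param img A [gray_image()].
#' @param angles_deg Projection angles in degrees (default 0..179 at 1
#'   degree steps).
#' @return `radon_transform()` a detector x angle matrix; `iradon_fbp()` a
#'   reconstructed matrix of the requested dimensions.
#' @export
radon_transform <- function(img, angles_deg = 0:179) {
  px <- unclass(as_gray_image(img))
  ndet <- 2L * as.integer(ceiling(sqrt(sum(dim(px)^2)) / 2)) + 1L
  cpp_radon(px, angles_deg * pi / 180, ndet)
}

#' @rdname radon_transform
#' @param sino A sinogram as returned by `radon_transform()`.
#' @param h,w Output dimensions.
#' @export
iradon_fbp <- function(sino, angles_deg, h, w) {
  ndet <- nrow(sino)
  nfft <- 2^ceiling(log2(2 * ndet))
  # Ram-Lak filter built in the spatial domain (avoids the DC bias of a
  # naive |f| ramp), then applied per angle in the frequency domain.
  hh <- numeric(nfft)
  hh[1] <- 0.25
  n <- seq(1, nfft / 2, by = 2)
  hh[1 + n] <- -1 / (pi * n)^2
  hh[nfft + 1 - n] <- -1 / (pi * n)^2
  Hf <- Re(stats::fft(hh))
  pad <- rbind(sino, matrix(0, nfft - ndet, ncol(sino)))
  filt <- Re(stats::mvfft(stats::mvfft(pad) * Hf, inverse = TRUE)) / nfft
  filt <- filt[seq_len(ndet), , drop = FALSE]
  cpp_backproject(filt, angles_deg * pi / 180, h, w)
}

#' Moire interference
#'
#' With probability `prob`, computes the Radon sinogram at 1-degree steps
#' over `[0, 180)`, reconstructs by filtered back-projection, and blends
#' `out = (1 - alpha) * img + alpha * reconstruction` with `alpha` drawn
#' uniformly in `[0.1, 0.3]`. The reconstruction's streak/ring artifacts
#' supply the moire-like interference.
#'
#' @param img A [gray_image()] with aspect ratio within `[0.5, 2]`.
#' @param prob Event probability.
#' @return A [gray_image()].
#' @export
apply_moire <- function(img, prob) {
  if (is_rgb(img) || length(dim(img)) != 2L) {
    stop("moire operates on 2-D grayscale images", call. = FALSE)
  }
  ar <- nrow(img) / ncol(img)
  if (ar < 0.5 || ar > 2) {
    stop("moire needs an aspect ratio within [0.5, 2]", call. = FALSE)
  }
  if (prob == 0 || stats::runif(1) >= prob) return(img)
  alpha <- stats::runif(1, 0.1, 0.3)
  angles <- 0:179
  recon <- iradon_fbp(radon_transform(img, angles), angles,
                      nrow(img), ncol(img))
  rewrap((1 - alpha) * unclass(img) + alpha * recon, img)
}

#' Poisson shot noise
#'
#' Zero-mean shot-noise perturbation: `out = clip(in + (P - lambda) / 255)`
#' with `P ~ Poisson(lambda)` per pixel, i.e. variance `lambda` on the
#' 0-255 scale.
#'
#' @param img Gray or RGB image.
#' @param lam Poisson lambda (>= 0).
#' @return The same kind of image.
#' @export
add_poisson_noise <- function(img, lam) {
  if (lam < 0) stop("`lam` must be >= 0", call. = FALSE)
  if (lam == 0) return(img)
  p <- stats::rpois(length(img), lam)
  out <- unclass(img) + (p - lam) / 255
  rewrap(array(out, dim(img) %||% c(nrow(img), ncol(img))), img)
}

#' JPEG compression round trip
#'
#' Encodes to JPEG at `quality = 100 - rate` with the compression rate drawn
#' uniformly in `rate_range` (percent), then decodes. Dimensions are
#' preserved; the codec's 8-bit quantization is the one place the pipeline
#' leaves the unit-interval representation.
#'
#' @param img Gray or RGB image.
#' @param rate_range Percent pair `c(low, high)` within `[0, 100]`.
#' @return The same kind of image.
#' @export
jpeg_compress <- function(img, rate_range = c(30, 70)) {
  if (length(rate_range) != 2L || any(rate_range < 0) ||
      any(rate_range > 100) || rate_range[1] > rate_range[2]) {
    stop("`rate_range` must be a low <= high pair within [0, 100]",
         call. = FALSE)
  }
  rate <- stats::runif(1, rate_range[1], rate_range[2])
  quality <- (100 - rate) / 100
  raw_jpg <- jpeg::writeJPEG(unclass(img), raw(), quality = quality)
  out <- jpeg::readJPEG(raw_jpg)
  if (is_rgb(img) && length(dim(out)) == 2L) {
    out <- array(rep(out, 3), c(dim(out), 3L))
  }
  if (!is_rgb(img) && length(dim(out)) == 3L) {
    out <- 0.299 * out[, , 1] + 0.587 * out[, , 2] + 0.114 * out[, , 3]
  }
  rewrap(out, img)
}

#' Simulate the full monitor-to-camera capture chain
#'
#' Converts to RGB and applies the eight operators in their enumeration
#' order -- (1) Gaussian noise, (2) saturation tint, (3) overexposure,
#' (4) contrast, (5) motion blur, (6) moire (on the luminance channel),
#' (7) Poisson noise, (8) JPEG compression -- then converts back to
#' grayscale. All stochastic draws come from a single seeded stream, so two
#' calls with equal seed and config are bit-identical. An explicit `order`
#' permutation can test alternative physical orderings of the optical path.
#'
#' @param img A [gray_image()].
#' @param config A [degradation_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @param order Integer permutation of 1:8 giving the stage order.
#' @return A [gray_image()] of the same dimensions.
#' @export
degrade <- function(img, config, seed = config$seed, order = 1:8) {
  stopifnot(inherits(config, "degradation_config"))
  validate_config(config)
  if (!identical(sort(as.integer(order)), 1:8)) {
    stop("`order` must be a permutation of 1:8", call. = FALSE)
  }
  img <- as_gray_image(img)
  stages <- list(
    gaussian = function(x) add_gaussian_noise(x, config$gaussian_mean,
                                              config$gaussian_var),
    saturation = function(x) apply_saturation_shift(x, config$saturation_prob,
                                                    config$white_yellow_ratio),
    overexposure = function(x) apply_overexposure(x, config$overexposure_mean,
                                                  config$overexposure_var),
    contrast = function(x) apply_contrast(x, config$contrast_intensity),
    motion = function(x) apply_motion_blur(x, config$motion_prob,
                                           config$motion_intensity),
    moire = function(x) {
      y <- to_gray(x)
      y2 <- apply_moire(y, config$moire_prob)
      delta <- unclass(y2) - unclass(y)
      out <- unclass(x)
      for (ch in 1:3) out[, , ch] <- out[, , ch] + delta
      rewrap(out, x)
    },
    poisson = function(x) add_poisson_noise(x, config$poisson_lambda),
    jpeg = function(x) {
      if (!config$apply_compression) return(x)
      jpeg_compress(x, config$compression_rate_range)
    }
  )
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    out <- to_rgb(img)
    for (i in order) {
      nm <- names(stages)[i]
      out <- tryCatch(stages[[i]](out), error = function(e) {
        stop("degradation stage '", nm, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    }
    to_gray(out)
  })
}
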