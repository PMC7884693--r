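#' Specification for a synthetic pseudo-radiograph dataset
#'
#' Default finding prevalences mirror the training-set prevalence of the
#' six major findings in a large public chest radiograph corpus
#' (cardiomegaly 19.7%, edema 11.8%, consolidation 4.7%, atelectasis
#' 20.0%, pneumothorax 4.7%, pleural effusion 23.7%), keeping the class
#' balance of synthetic experiments comparable to the real task.
#'
#' @param n_images Number of images (>= 1).
#' @param side Image side length in pixels (default 320; minimum 64).
#' @param finding_prevalences Named vector of per-finding prevalences over
#'   the six major findings.
#' @param seed RNG seed; with the spec it fully determines the dataset.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_images, side = 320L,
                           finding_prevalences = c(
                             cardiomegaly = 0.197, edema = 0.118,
                             consolidation = 0.047, atelectasis = 0.200,
                             pneumothorax = 0.047, pleural_effusion = 0.237),
                           seed = 0L) {
  if (n_images < 1L) stop("`n_images` must be >= 1", call. = FALSE)
  if (side < 64L) stop("`side` must be >= 64 pixels", call. = FALSE)
  missing <- setdiff(major_findings(), names(finding_prevalences))
  if (length(missing) > 0) {
    stop("missing prevalence for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(finding_prevalences < 0 | finding_prevalences > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_images = as.integer(n_images), side = as.integer(side),
                 finding_prevalences = finding_prevalences[major_findings()],
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Soft-edged ellipse mask: 1 inside, 0 outside, smooth transition.
# Centre and semi-axes in normalized [0,1] image coordinates.
ellipse_mask <- function(xg, yg, cx, cy, ax, ay, softness = 0.08) {
  e <- ((xg - cx) / ax)^2 + ((yg - cy) / ay)^2
  1 / (1 + exp((e - 1) / softness))
}

# Smoothed uniform noise field for soft-tissue texture.
texture_field <- function(side, amplitude) {
  z <- matrix(stats::runif(side * side, -1, 1), side, side)
  k <- matrix(1 / 49, 7, 7)
  z <- cpp_convolve2_reflect(cpp_convolve2_reflect(z, k), k)
  amplitude * z / max(abs(z))
}

#' Render one pseudo-radiograph with planted findings
#'
#' Draws a deterministic chest-like template -- dark lung fields, a bright
#' mediastinal column, a cardiac silhouette, rib bands and smoothed noise
#' texture -- then plants each finding drawn from its prevalence as an
#' analytically parameterized shape: cardiomegaly as an enlarged cardiac
#' ellipse (width fraction > 0.5 of the thorax), pleural effusion as a
#' bright basal wedge, consolidation as a mid-lung blob, edema as diffuse
#' perihilar haze, atelectasis as a linear band, pneumothorax as a dark
#' peripheral rim. Labels are exact by construction.
#'
#' @param spec A [synthetic_spec()].
#' @param index Image index (1-based); `(spec$seed, index)` fully
#'   determines the output.
#' @return A list: `image` (a [gray_image()]), `labels` (named 0/1 vector
#'   over the six findings plus `no_finding`), `provenance` (the planted
#'   shape parameters).
#' @export
generate_pseudo_cxr <- function(spec, index) {
  stopifnot(inherits(spec, "synthetic_spec"))
  s <- spec$side
  withr::with_seed((spec$seed * 131071L + as.integer(index)) %% 2147483647L, {
    prev <- spec$finding_prevalences
    present <- stats::setNames(stats::runif(length(prev)) < prev, names(prev))

    xs <- (seq_len(s) - 0.5) / s
    xg <- matrix(xs, s, s, byrow = TRUE)
    yg <- matrix(xs, s, s)

    img <- 0.32 + 0.1 * yg                      # body with caudal gradient
    lungL <- ellipse_mask(xg, yg, 0.31, 0.46, 0.17, 0.27)
    lungR <- ellipse_mask(xg, yg, 0.69, 0.46, 0.17, 0.27)
    lungs <- pmin(lungL + lungR, 1)
    img <- img - 0.22 * lungs                   # radiolucent lung fields
    img <- img + 0.28 * ellipse_mask(xg, yg, 0.5, 0.45, 0.09, 0.33)  # spine

    # cardiac silhouette; width fraction of the 0.8-wide thorax decides
    # cardiomegaly (> 0.5 when planted, < 0.45 otherwise)
    thorax_w <- 0.8
    heart_frac <- if (present["cardiomegaly"]) {
      stats::runif(1, 0.55, 0.65)
    } else {
      stats::runif(1, 0.34, 0.43)
    }
    heart_ax <- heart_frac * thorax_w / 2
    img <- img + 0.24 * ellipse_mask(xg, yg, 0.54, 0.6, heart_ax, 0.16)

    ribs <- 0.035 * sin(2 * pi * (yg * 9 + 0.12 * xg)) * lungs
    img <- img + ribs + texture_field(s, 0.03)

    prov <- list(heart_width_fraction = heart_frac)

    if (present["pleural_effusion"]) {
      sideL <- stats::runif(1) < 0.5
      y0 <- stats::runif(1, 0.58, 0.64)
      mask <- (if (sideL) lungL else lungR) *
        (1 / (1 + exp(-(yg - y0) / 0.02)))
      img <- img + 0.30 * mask
      prov$effusion <- list(left = sideL, level = y0)
    }
    if (present["consolidation"]) {
      sideL <- stats::runif(1) < 0.5
      cx <- if (sideL) stats::runif(1, 0.25, 0.37) else stats::runif(1, 0.63, 0.75)
      cy <- stats::runif(1, 0.38, 0.52)
      sg <- stats::runif(1, 0.05, 0.08)
      img <- img + 0.30 * exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * sg^2))
      prov$consolidation <- list(cx = cx, cy = cy, sigma = sg)
    }
    if (present["edema"]) {
      amp <- stats::runif(1, 0.14, 0.2)
      img <- img + amp * exp(-((xg - 0.5)^2 + (yg - 0.47)^2) / (2 * 0.22^2)) *
        lungs
      prov$edema <- list(amplitude = amp)
    }
    if (present["atelectasis"]) {
      sideL <- stats::runif(1) < 0.5
      cx <- if (sideL) 0.31 else 0.69
      cy <- stats::runif(1, 0.4, 0.55)
      th <- stats::runif(1, -0.3, 0.3)
      band <- exp(-((yg - cy) - th * (xg - cx))^2 / (2 * 0.012^2)) *
        (if (sideL) lungL else lungR)
      img <- img + 0.26 * band
      prov$atelectasis <- list(left = sideL, cy = cy, slope = th)
    }
    if (present["pneumothorax"]) {
      sideL <- stats::runif(1) < 0.5
      cx <- if (sideL) 0.31 else 0.69
      outer <- ellipse_mask(xg, yg, cx, 0.46, 0.17, 0.27, 0.03)
      inner <- ellipse_mask(xg, yg, cx, 0.46, 0.125, 0.21, 0.03)
      img <- img - 0.18 * pmax(outer - inner, 0)
      prov$pneumothorax <- list(left = sideL)
    }

    labels <- c(as.integer(present),
                no_finding = as.integer(!any(present)))
    names(labels) <- c(names(present), "no_finding")
    list(image = gray_image(clip01(img)), labels = labels, provenance = prov)
  })
}

#' Generate a labeled synthetic dataset
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_dataset`: `images` (list of [gray_image()]s),
#'   `labels` (tibble: `image_id` + six findings + `no_finding`), and
#'   per-image `provenance`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  out <- purrr::map(seq_len(spec$n_images), function(i) {
    generate_pseudo_cxr(spec, i)
  })
  labels <- dplyr::bind_rows(purrr::map(out, function(x) {
    tibble::as_tibble(as.list(x$labels))
  }))
  labels <- dplyr::bind_cols(
    tibble::tibble(image_id = sprintf("img_%05d", seq_len(spec$n_images))),
    labels
  )
  structure(list(images = purrr::map(out, "image"), labels = labels,
                 provenance = purrr::map(out, "provenance"), spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %d images of %dx%d, seed %d>\n",
              length(x$images), x$spec$side, x$spec$side, x$spec$seed))
  invisible(x)
}

#' Ground truth for the capture simulator
#'
#' @param config The [degradation_config()] applied between the geometric
#'   warp and its rectification.
#' @param max_rotation_deg Rotation drawn uniformly in
#'   `[-max_rotation_deg, max_rotation_deg]`; must stay within 7 degrees,
#'   the training-augmentation convention.
#' @param perspective_jitter Corner jitter as a fraction of the image side.
#' @param seed RNG seed.
#' @return A `capture_truth` object.
#' @export
capture_truth <- function(config = degradation_config(),
                          max_rotation_deg = 7, perspective_jitter = 0.02,
                          seed = 0L) {
  stopifnot(inherits(config, "degradation_config"))
  if (max_rotation_deg < 0 || max_rotation_deg > 7) {
    stop("`max_rotation_deg` must lie in [0, 7]", call. = FALSE)
  }
  if (perspective_jitter < 0 || perspective_jitter > 0.1) {
    stop("`perspective_jitter` must lie in [0, 0.1]", call. = FALSE)
  }
  structure(list(config = config, max_rotation_deg = max_rotation_deg,
                 perspective_jitter = perspective_jitter,
                 seed = as.integer(seed)),
            class = "capture_truth")
}

# Direct linear transform: 3x3 homography mapping src (x, y) points onto
# dst points (4 correspondences).
homography_from_points <- function(src, dst) {
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]
    u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Simulate the capture of a displayed radiograph, with rectification
#'
#' Applies a small random rotation and perspective warp (the hand-held
#' camera pose), runs the degradation pipeline on the warped frame, then
#' rectifies with the exact inverse warp -- emulating automatic
#' document-alignment of the photograph -- leaving at most about one pixel
#' of residual misregistration from resampling. Finally resizes to
#' `out_side`.
#'
#' @param img A [gray_image()].
#' @param truth A [capture_truth()].
#' @param seed RNG seed (default `truth$seed`); vary per image to emulate
#'   independent captures of a shared device setup.
#' @param out_side Output side length (default: the input's).
#' @return A [gray_image()].
#' @export
simulate_capture <- function(img, truth, seed = truth$seed,
                             out_side = nrow(img)) {
  stopifnot(inherits(truth, "capture_truth"))
  img <- as_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  seed <- as.integer(seed) %% 2147483647L
  geo <- withr::with_seed(seed, {
    theta <- if (truth$max_rotation_deg > 0) {
      stats::runif(1, -truth$max_rotation_deg, truth$max_rotation_deg) * pi / 180
    } else 0
    jit <- if (truth$perspective_jitter > 0) {
      matrix(stats::runif(8, -truth$perspective_jitter,
                          truth$perspective_jitter) * max(h, w), 4, 2)
    } else matrix(0, 4, 2)
    list(theta = theta, jit = jit)
  })
  identity_geo <- geo$theta == 0 && all(geo$jit == 0)
  if (identity_geo) {
    warped <- img
  } else {
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    ct <- cos(geo$theta); st <- sin(geo$theta)
    H_rot <- matrix(c(ct, -st, cx - ct * cx + st * cy,
                      st, ct, cy - st * cx - ct * cy,
                      0, 0, 1), 3, 3, byrow = TRUE)
    corners <- matrix(c(0, 0, w - 1, 0, w - 1, h - 1, 0, h - 1),
                      4, 2, byrow = TRUE)
    H_persp <- homography_from_points(corners, corners + geo$jit)
    H <- H_persp %*% H_rot
    warped <- rewrap(cpp_warp_projective(unclass(img), solve(H), h, w,
                                         fill = 0.06, clamp_edges = FALSE),
                     img)
  }
  degraded <- degrade(warped, truth$config, seed = (seed + 1L) %% 2147483647L)
  rectified <- if (identity_geo) degraded else {
    rewrap(cpp_warp_projective(unclass(degraded), H, h, w,
                               fill = 0.06, clamp_edges = TRUE), img)
  }
  resize_to(rectified, out_side)
}

#' @rdname capture_truth
#' @param x A `capture_truth`.
#' @param path File path for the JSON serialization.
#' @export
write_capture_truth <- function(x, path) {
  stopifnot(inherits(x, "capture_truth"))
  out <- list(config = unclass(x$config),
              max_rotation_deg = x$max_rotation_deg,
              perspective_jitter = x$perspective_jitter, seed = x$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname capture_truth
#' @export
read_capture_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  capture_truth(do.call(degradation_config, as.list(x$config)),
                x$max_rotation_deg, x$perspective_jitter, x$seed)
}
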