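#' Construct a grayscale image
#'
#' Images are stored as plain numeric matrices of intensities on the unit
#' interval, with class `gray_image`. All operators in the package keep
#' intensities in `[0, 1]`; conversion to 8 bits happens only at file I/O
#' and inside the JPEG compression operator.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @return A `gray_image` object (a classed numeric matrix).
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 8L || ncol(pixels) < 8L) {
    stop("image must be at least 8x8 pixels, got ",
         nrow(pixels), "x", ncol(pixels), call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("image intensities must all be finite", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  }
  structure(unclass(pixels), class = c("gray_image", "matrix", "array"))
}

#' Construct an RGB image
#'
#' @param pixels Numeric array `height x width x 3` of intensities in `[0, 1]`.
#' @return An `rgb_image` object (a classed numeric array).
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be a height x width x 3 numeric array", call. = FALSE)
  }
  if (dim(pixels)[1] < 8L || dim(pixels)[2] < 8L) {
    stop("image must be at least 8x8 pixels", call. = FALSE)
  }
  if (!all(is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 1) {
    stop("image intensities must be finite and lie in [0, 1]", call. = FALSE)
  }
  structure(unclass(pixels), class = c("rgb_image", "array"))
}

is_gray <- function(img) inherits(img, "gray_image") ||
  (is.matrix(img) && is.numeric(img))
is_rgb <- function(img) inherits(img, "rgb_image") ||
  (is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L)

as_gray_image <- function(img) {
  if (inherits(img, "gray_image")) img else gray_image(as.matrix(img))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Re-wrap a raw matrix/array as the same image class as `template`, clipping
# to the unit interval.
rewrap <- function(pixels, template) {
  pixels <- clip01(pixels)
  if (is_rgb(template)) {
    structure(pixels, class = c("rgb_image", "array"))
  } else {
    structure(pixels, class = c("gray_image", "matrix", "array"))
  }
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, range [%.3f, %.3f]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d x 3, range [%.3f, %.3f]>\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' Load an image file as a grayscale image
#'
#' Reads a PNG or JPEG file, rescales 8-bit intensities to `[0, 1]`, and
#' converts colour inputs to luminance with the fixed weights
#' (0.299, 0.587, 0.114).
#'
#' @param path Path to a PNG or JPEG file.
#' @return A [gray_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file does not exist: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      jpg = ,
      jpeg = jpeg::readJPEG(path),
      stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
    ),
    error = function(e) {
      stop("failed to read image ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(px) == 0) stop("zero-size image: ", path, call. = FALSE)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] >= 3L) {
      px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    } else {
      px <- px[, , 1]
    }
  }
  gray_image(clip01(px))
}

#' Write a grayscale image as an 8-bit PNG
#'
#' @param img A [gray_image()].
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  img <- as_gray_image(img)
  png::writePNG(unclass(img), target = path)
  invisible(path)
}

#' Histogram equalization
#'
#' Classic cumulative-distribution mapping over 256 equal-width bins on
#' `[0, 1]`: each occupied level is mapped to the empirical CDF at its bin.
#' A constant image is returned unchanged. Deterministic; applying the
#' operation twice changes each pixel by at most one quantization step.
#'
#' @param img A [gray_image()].
#' @param bins Number of histogram bins (default 256, matching 8-bit sources).
#' @return An equalized [gray_image()].
#' @export
equalize_histogram <- function(img, bins = 256L) {
  img <- as_gray_image(img)
  if (max(img) - min(img) <= 0) return(img)
  idx <- pmin(pmax(floor(unclass(img) * bins), 0), bins - 1L) + 1L
  counts <- tabulate(idx, nbins = bins)
  cdf <- cumsum(counts) / length(img)
  out <- matrix(cdf[idx], nrow = nrow(img), ncol = ncol(img))
  gray_image(clip01(out))
}

#' Resize an image to a square raster
#'
#' Bilinear interpolation with pixel-centre alignment. Resizing to the
#' current dimensions is an exact identity.
#'
#' @param img A [gray_image()] or [rgb_image()].
#' @param side Output side length in pixels (>= 8).
#' @return The same kind of image, `side x side`.
#' @export
resize_to <- function(img, side) {
  side <- as.integer(side)
  if (is.na(side) || side < 8L) {
    stop("`side` must be a positive integer >= 8", call. = FALSE)
  }
  if (is_rgb(img)) {
    d <- dim(img)
    if (d[1] == side && d[2] == side) return(img)
    out <- array(0, c(side, side, 3L))
    for (ch in 1:3) {
      out[, , ch] <- cpp_resize_bilinear(img[, , ch], side, side)
    }
    return(rewrap(out, img))
  }
  img <- as_gray_image(img)
  if (nrow(img) == side && ncol(img) == side) return(img)
  rewrap(cpp_resize_bilinear(unclass(img), side, side), img)
}

#' Convert between grayscale and RGB
#'
#' `to_rgb()` replicates the gray channel three times; `to_gray()` collapses
#' with the fixed luminance weights (0.299, 0.587, 0.114), which sum to one,
#' so the round trip gray -> rgb -> gray is exact.
#'
#' @param img A [gray_image()] (for `to_rgb`) or [rgb_image()] (for `to_gray`).
#' @return The converted image.
#' @export
to_rgb <- function(img) {
  img <- as_gray_image(img)
  px <- unclass(img)
  rgb_image(array(c(px, px, px), c(nrow(px), ncol(px), 3L)))
}

#' @rdname to_rgb
#' @export
to_gray <- function(img) {
  if (!is_rgb(img)) stop("`img` must be an rgb_image", call. = FALSE)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  if (identical(r, g) && identical(g, b)) return(gray_image(r))
  gray_image(clip01(0.299 * r + 0.587 * g + 0.114 * b))
}
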