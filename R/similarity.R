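# Cached complex log-Gabor filter banks, keyed by (h, w, levels, n_orient).
.filter_cache <- new.env(parent = emptyenv())

# Frequency-domain complex log-Gabor bank: `levels` octave-spaced scales x
# `n_orient` orientations, one-sided in frequency so the spatial
# coefficients are complex analytic signals (magnitude + phase), plus one
# low-pass residual band so local luminance takes part in the comparison
# (the analogue of SSIM's luminance term).
loggabor_bank <- function(h, w, levels = 4L, n_orient = 6L) {
  key <- paste(h, w, levels, n_orient, sep = "x")
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  fy <- (seq_len(h) - 1) / h
  fy[fy >= 0.5] <- fy[fy >= 0.5] - 1
  fx <- (seq_len(w) - 1) / w
  fx[fx >= 0.5] <- fx[fx >= 0.5] - 1
  u <- matrix(fx, h, w, byrow = TRUE)
  v <- matrix(fy, h, w)
  r <- sqrt(u^2 + v^2)
  r[1, 1] <- 1  # silence log(0); the DC entry is zeroed below
  theta <- atan2(v, u)
  sigma_r <- 0.65       # radial bandwidth ratio (about two octaves)
  sigma_t <- 0.6545     # angular spread for six orientations
  bank <- vector("list", levels * n_orient + 1L)
  i <- 0L
  for (s in seq_len(levels)) {
    f0 <- (1 / 3) / 2^(s - 1)
    radial <- exp(-(log(r / f0))^2 / (2 * log(sigma_r)^2))
    radial[1, 1] <- 0
    for (o in seq_len(n_orient)) {
      t0 <- (o - 1) * pi / n_orient
      d <- atan2(sin(theta - t0), cos(theta - t0))
      angular <- exp(-d^2 / (2 * sigma_t^2))
      i <- i + 1L
      bank[[i]] <- radial * angular
    }
  }
  f_lp <- (1 / 3) / 2^(levels - 1)
  bank[[i + 1L]] <- exp(-r^2 / (2 * f_lp^2))
  bank[[i + 1L]][1, 1] <- 1
  .filter_cache[[key]] <- bank
  bank
}

# Fast box filter (k x k moving sum) via integral images.
boxfilt <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  cs <- matrix(0, h + 1L, w + 1L)  # integral image
  cs[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  r1 <- pmax(seq_len(h) - k %/% 2 - 1, 0) + 1
  r2 <- pmin(seq_len(h) + (k - 1) %/% 2, h) + 1
  c1 <- pmax(seq_len(w) - k %/% 2 - 1, 0) + 1
  c2 <- pmin(seq_len(w) + (k - 1) %/% 2, w) + 1
  cs[r2, c2] - cs[r1, c2] - cs[r2, c1] + cs[r1, c1]
}

#' Complex wavelet structural similarity (CW-SSIM)
#'
#' Decomposes both images with a complex log-Gabor filter bank (`levels`
#' octave-spaced scales, six orientations, plus a low-pass residual band
#' that lets local luminance shifts register) and evaluates, over 7x7
#' sliding windows `w` of each subband, `(2 |sum_w a conj(b)| + K) /
#' (sum_w |a|^2 + sum_w |b|^2 + K)`, averaging over windows and subbands.
#' Because the statistic depends on coefficient magnitudes and *relative*
#' phase consistency, it is far less sensitive to small translations than
#' intensity-domain SSIM. The score lies in `[0, 1]`, is symmetric, and
#' equals 1 for identical images.
#'
#' @param a,b Equal-sized [gray_image()]s, at least 64x64.
#' @param levels Number of dyadic scales (default 4).
#' @param stabilizer Stabilizing constant K (default 0.01).
#' @return A similarity score in `[0, 1]`.
#' @export
cw_ssim <- function(a, b, levels = 4L, stabilizer = 0.01) {
  a <- as_gray_image(a); b <- as_gray_image(b)
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("dimension mismatch: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  }
  if (nrow(a) < 64L || ncol(a) < 64L) {
    stop("cw_ssim needs images of at least 64x64 pixels", call. = FALSE)
  }
  fa <- stats::fft(unclass(a))
  fb <- stats::fft(unclass(b))
  bank <- loggabor_bank(nrow(a), ncol(a), levels)
  n <- length(a)
  scores <- vapply(bank, function(flt) {
    ca <- stats::fft(fa * flt, inverse = TRUE) / n
    cb <- stats::fft(fb * flt, inverse = TRUE) / n
    cross <- ca * Conj(cb)
    num <- 2 * sqrt(boxfilt(Re(cross), 7L)^2 + boxfilt(Im(cross), 7L)^2) +
      stabilizer
    den <- boxfilt(Mod(ca)^2, 7L) + boxfilt(Mod(cb)^2, 7L) + stabilizer
    mean(num / den)
  }, numeric(1))
  mean(scores)
}

#' Intensity histogram
#'
#' Counts over `bins` equal-width bins on `[0, 1]`, optionally normalized to
#' a probability vector.
#'
#' @param img A [gray_image()].
#' @param bins Number of bins (default 256, matching 8-bit provenance).
#' @param normalize Normalize counts to sum to one?
#' @return An `intensity_histogram`: list with `bin_counts` and `normalized`.
#' @export
intensity_histogram <- function(img, bins = 256L, normalize = TRUE) {
  if (bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  img <- as_gray_image(img)
  idx <- pmin(pmax(floor(unclass(img) * bins), 0), bins - 1L) + 1L
  counts <- as.numeric(tabulate(idx, nbins = bins))
  if (normalize) counts <- counts / sum(counts)
  structure(list(bin_counts = counts, normalized = normalize),
            class = "intensity_histogram")
}

#' Bhattacharyya distance between two normalized histograms
#'
#' `d = sqrt(1 - sum_i sqrt(p_i q_i))`, in `[0, 1]`: 0 for identical
#' histograms, 1 for histograms with disjoint support.
#'
#' @param h1,h2 Normalized [intensity_histogram()]s with equal bin counts.
#' @return The distance, a scalar in `[0, 1]`.
#' @export
bhattacharyya_distance <- function(h1, h2) {
  for (h in list(h1, h2)) {
    if (!inherits(h, "intensity_histogram") || !isTRUE(h$normalized)) {
      stop("both inputs must be normalized intensity_histogram objects",
           call. = FALSE)
    }
  }
  if (length(h1$bin_counts) != length(h2$bin_counts)) {
    stop("histograms must have equal bin counts", call. = FALSE)
  }
  bc <- sum(sqrt(h1$bin_counts * h2$bin_counts))
  sqrt(max(0, 1 - bc))
}

#' Compare a set of augmented images against reference photographs
#'
#' Scores augmented images against references with both calibration
#' objectives: CW-SSIM (higher = more photograph-like relative to the
#' reference) and the Bhattacharyya distance between intensity histograms
#' (lower = closer). `matched` pairing scores pair `i = (augmented[i],
#' references[i])`; `cross` pairing scores each augmented image against its
#' most favourable reference under each metric.
#'
#' @param augmented,references Lists of [gray_image()]s.
#' @param pairing `"matched"` (default) or `"cross"`.
#' @param metrics Which metrics to compute (default both; calibration
#'   passes just its objective to avoid paying for the other).
#' @param levels,stabilizer Passed to [cw_ssim()].
#' @return A `similarity_report`: per-pair scores, their means, and
#'   `n_pairs`. `tidy()` turns it into a tibble.
#' @export
compare_sets <- function(augmented, references, pairing = c("matched", "cross"),
                         metrics = c("cwssim", "bhattacharyya"),
                         levels = 4L, stabilizer = 0.01) {
  pairing <- match.arg(pairing)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (length(augmented) == 0 || length(references) == 0) {
    stop("`augmented` and `references` must be non-empty lists",
         call. = FALSE)
  }
  if (pairing == "matched" && length(augmented) != length(references)) {
    stop("matched pairing requires equal list lengths (",
         length(augmented), " vs ", length(references), ")", call. = FALSE)
  }
  want_cw <- "cwssim" %in% metrics
  want_bh <- "bhattacharyya" %in% metrics
  ref_hists <- if (want_bh) lapply(references, intensity_histogram)
  na <- rep(NA_real_, length(augmented))
  if (pairing == "matched") {
    cw <- if (want_cw) purrr::map2_dbl(augmented, references, cw_ssim,
                                       levels = levels,
                                       stabilizer = stabilizer) else na
    bh <- if (want_bh) purrr::map2_dbl(augmented, ref_hists, function(a, rh) {
      bhattacharyya_distance(intensity_histogram(a), rh)
    }) else na
  } else {
    cw <- if (want_cw) purrr::map_dbl(augmented, function(a) {
      max(purrr::map_dbl(references, cw_ssim, b = a,
                         levels = levels, stabilizer = stabilizer))
    }) else na
    bh <- if (want_bh) purrr::map_dbl(augmented, function(a) {
      ah <- intensity_histogram(a)
      min(purrr::map_dbl(ref_hists, bhattacharyya_distance, h1 = ah))
    }) else na
  }
  structure(
    list(per_pair_cwssim = cw, per_pair_bhattacharyya = bh,
         mean_cwssim = mean(cw), mean_bhattacharyya = mean(bh),
         n_pairs = length(cw), pairing = pairing),
    class = "similarity_report"
  )
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(
    "<similarity_report: %d pairs (%s), mean CW-SSIM %.4f, mean Bhattacharyya %.4f>\n",
    x$n_pairs, x$pairing, x$mean_cwssim, x$mean_bhattacharyya))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.similarity_report <- function(x, ...) {
  tibble::tibble(
    pair = seq_len(x$n_pairs),
    cwssim = x$per_pair_cwssim,
    bhattacharyya = x$per_pair_bhattacharyya
  )
}

#' @export
glance.similarity_report <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs,
    pairing = x$pairing,
    mean_cwssim = x$mean_cwssim,
    mean_bhattacharyya = x$mean_bhattacharyya
  )
}
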