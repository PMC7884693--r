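# Smoothed random texture image: enough structure for codec and
# similarity tests without shipping any binary fixture.
make_texture <- function(side = 64L, seed = 1L) {
  withr::with_seed(seed, {
    z <- matrix(stats::runif(side * side), side, side)
    k <- matrix(1 / 25, 5, 5)
    z <- photoreca:::cpp_convolve2_reflect(z, k)
    z <- (z - min(z)) / (max(z) - min(z))
    gray_image(0.1 + 0.8 * z)
  })
}

# Piecewise-constant ellipse phantom for tomography round trips.
make_phantom <- function(side = 128L) {
  xs <- (seq_len(side) - 0.5) / side
  xg <- matrix(xs, side, side, byrow = TRUE)
  yg <- matrix(xs, side, side)
  ell <- function(cx, cy, ax, ay) {
    (((xg - cx) / ax)^2 + ((yg - cy) / ay)^2 <= 1) * 1
  }
  ph <- 0.2 + 0.5 * ell(0.5, 0.5, 0.35, 0.45) - 0.2 * ell(0.42, 0.5, 0.1, 0.25) -
    0.2 * ell(0.6, 0.45, 0.08, 0.2) + 0.2 * ell(0.5, 0.7, 0.05, 0.05)
  gray_image(pmin(pmax(ph, 0), 1))
}

# Plain intensity-domain SSIM over sliding windows -- the oracle that
# CW-SSIM must beat under small translations.
plain_ssim <- function(a, b, win = 8L) {
  a <- unclass(a); b <- unclass(b)
  c1 <- (0.01)^2; c2 <- (0.03)^2
  n <- win * win
  vals <- c()
  for (r in seq(1, nrow(a) - win + 1, by = win)) {
    for (cc in seq(1, ncol(a) - win + 1, by = win)) {
      wa <- a[r:(r + win - 1), cc:(cc + win - 1)]
      wb <- b[r:(r + win - 1), cc:(cc + win - 1)]
      ma <- mean(wa); mb <- mean(wb)
      va <- stats::var(as.numeric(wa)); vb <- stats::var(as.numeric(wb))
      cab <- stats::cov(as.numeric(wa), as.numeric(wb))
      vals <- c(vals, ((2 * ma * mb + c1) * (2 * cab + c2)) /
                  ((ma^2 + mb^2 + c1) * (va + vb + c2)))
    }
  }
  mean(vals)
}

# Exhaustive concordant-pair AUROC oracle (ties one half).
auroc_pair_oracle <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Welch's t from the textbook formula.
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# ICC(A,1) from stats::aov mean squares -- the independent ANOVA route.
icc_aov_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.numeric(m),
                  subject = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  av <- summary(stats::aov(y ~ subject + rater, data = d))[[1]]
  msr <- av["subject", "Mean Sq"]
  msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Consistency-form ICC(C,1) for the absolute-vs-consistency ordering check.
icc_consistency_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.numeric(m),
                  subject = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  av <- summary(stats::aov(y ~ subject + rater, data = d))[[1]]
  msr <- av["subject", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse)
}

make_histogram <- function(p) {
  structure(list(bin_counts = p, normalized = TRUE),
            class = "intensity_histogram")
}
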