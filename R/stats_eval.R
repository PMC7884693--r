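#' The six major radiological findings
#'
#' The findings used for averaged-AUROC reporting: cardiomegaly, edema,
#' consolidation, atelectasis, pneumothorax, pleural effusion.
#'
#' @return Character vector of length six.
#' @export
major_findings <- function() {
  c("cardiomegaly", "edema", "consolidation", "atelectasis",
    "pneumothorax", "pleural_effusion")
}

#' One-versus-all AUROC
#'
#' Rank-based (Mann-Whitney) estimate: the U statistic divided by
#' `n_pos * n_neg`, with ties counted one half. Equals the probability that
#' a random positive outscores a random negative.
#'
#' @param scores Numeric prediction scores.
#' @param truth Binary ground truth (0/1), same length.
#' @return The AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(scores) != length(truth)) {
    stop("`scores` and `truth` must have equal length", call. = FALSE)
  }
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC is undefined when only one class is present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[truth == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Threshold-based binary classification metrics
#'
#' Sensitivity, specificity, F1 and accuracy at a fixed score threshold
#' (prediction positive when `score >= threshold`). When no positive
#' predictions and no positive truths exist, F1 is undefined and reported
#' as `NA` with a warning.
#'
#' @param scores Numeric prediction scores.
#' @param truth Binary ground truth (0/1).
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row tibble with `sensitivity`, `specificity`, `f1`,
#'   `accuracy`.
#' @export
binary_metrics <- function(scores, truth, threshold = 0.5) {
  truth <- as.integer(truth)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else {
    warning("F1 undefined: no positive truths or predictions",
            call. = FALSE)
    NA_real_
  }
  tibble::tibble(sensitivity = sens, specificity = spec, f1 = f1,
                 accuracy = (tp + tn) / length(truth))
}

#' Bootstrap AUROC with percentile confidence interval
#'
#' Resamples image indices with replacement `n_boot` times; resamples that
#' contain a single truth class are redrawn. The confidence interval is the
#' (2.5, 97.5) percentile interval of the bootstrap AUROCs.
#'
#' @param scores Numeric prediction scores.
#' @param truth Binary ground truth (0/1), both classes present.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return List with `samples` (length `n_boot`), `auroc` (point estimate),
#'   `ci_low`, `ci_high`.
#' @export
bootstrap_auroc <- function(scores, truth, n_boot = 1000L, seed = 0L) {
  if (n_boot < 2L) stop("`n_boot` must be >= 2", call. = FALSE)
  truth <- as.integer(truth)
  point <- auroc(scores, truth)
  n <- length(scores)
  samples <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(truth[idx])) == 2L) break
      }
      auroc(scores[idx], truth[idx])
    }, numeric(1))
  })
  ci <- unname(stats::quantile(samples, c(0.025, 0.975), type = 7))
  list(samples = samples, auroc = point, ci_low = ci[1], ci_high = ci[2])
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, two-sided. Used to compare two sets of bootstrap AUROCs. Two
#' identical constant samples give `t = 0, p = 1`; unequal constant
#' samples are flagged with `p = 0`.
#'
#' @param samples_a,samples_b Numeric vectors (length >= 2 each).
#' @return A one-row tibble with `t_statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(samples_a, samples_b) {
  if (length(samples_a) < 2L || length(samples_b) < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(samples_a) == 0 && stats::var(samples_b) == 0) {
    if (mean(samples_a) == mean(samples_b)) {
      return(tibble::tibble(t_statistic = 0, df = NA_real_, p_value = 1))
    }
    warning("both samples constant but unequal; p-value degenerates to 0",
            call. = FALSE)
    return(tibble::tibble(t_statistic = Inf, df = NA_real_, p_value = 0))
  }
  tt <- stats::t.test(samples_a, samples_b, var.equal = FALSE)
  tibble::tibble(t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value)
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way mixed-effects, single-measurement, absolute-agreement ICC from
#' the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + (k / n)(MSC - MSE))`, with the 95%
#' confidence interval from the McGraw-Wong F-distribution construction.
#' Subjects are rows (e.g. radiographs), raters are columns (e.g. device
#' settings).
#'
#' @param m Numeric matrix, subjects x raters, no missing cells.
#' @param conf_level Confidence level (default 0.95).
#' @return An `icc_result`: `icc`, `ci_low`, `ci_high`, the ANOVA mean
#'   squares, and the model descriptor string.
#' @export
icc_single_absolute <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells are not allowed", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  }
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_total == 0) {
    return(structure(list(icc = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, msr = msr, msc = msc,
                          mse = mse,
                          model_descriptor = icc_model_descriptor()),
                     class = "icc_result"))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = icc, ci_low = lower, ci_high = upper,
                 msr = msr, msc = msc, mse = mse,
                 model_descriptor = icc_model_descriptor()),
            class = "icc_result")
}

icc_model_descriptor <- function() {
  "two-way mixed, single measurement, absolute agreement"
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result: ICC(A,1) = %.4f [%.4f, %.4f] (%s)>\n",
              x$icc, x$ci_low, x$ci_high, x$model_descriptor))
  invisible(x)
}

#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 msr = x$msr, msc = x$msc, mse = x$mse)
}

#' Compare two bootstrap AUROC samples
#'
#' Convenience wrapper pairing [bootstrap_auroc()] with [welch_t_test()],
#' the protocol used throughout the evaluation: bootstrap the test data,
#' collect AUROCs for both models, then a two-sided Welch test.
#'
#' @param scores_a,scores_b Score vectors of the two models on the same
#'   test set.
#' @param truth Shared binary ground truth.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed RNG seed (the two models resample independently from
#'   `seed` and `seed + 1`).
#' @return A `bootstrap_comparison`: both sample vectors, `t_statistic`,
#'   `p_value`, `n_boot`, `seed`.
#' @export
compare_bootstrap_auroc <- function(scores_a, scores_b, truth,
                                    n_boot = 1000L, seed = 0L) {
  ba <- bootstrap_auroc(scores_a, truth, n_boot, seed)
  bb <- bootstrap_auroc(scores_b, truth, n_boot, seed + 1L)
  tt <- welch_t_test(ba$samples, bb$samples)
  structure(list(samples_a = ba$samples, samples_b = bb$samples,
                 t_statistic = tt$t_statistic, p_value = tt$p_value,
                 n_boot = n_boot, seed = seed),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_comparison: %d resamples, t = %.3f, p = %.3g>\n",
    x$n_boot, x$t_statistic, x$p_value))
  invisible(x)
}

# Half-up rounding (round(0.005, 2) in IEEE arithmetic is not always up).
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5 + 1e-12) / 10^digits
}

#' Average AUROC over the six major findings
#'
#' Arithmetic mean of the per-finding point AUROCs for one model, rounded
#' half-up to two decimals -- the aggregation used for table-style
#' reporting.
#'
#' @param table A data frame with columns `finding`, `model`, `auroc` (as
#'   returned by [cxr_table1()]).
#' @param model Model name to aggregate.
#' @param findings Findings to average over (default the six major
#'   findings, all of which must be present).
#' @return The rounded mean AUROC.
#' @export
aggregate_mean_auroc <- function(table, model, findings = major_findings()) {
  sub <- table[table$model == model, , drop = FALSE]
  missing <- setdiff(findings, sub$finding)
  if (length(missing) > 0) {
    stop("missing finding(s) for model '", model, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- sub$auroc[match(findings, sub$finding)]
  round_half_up(mean(vals), 2L)
}

#' Published per-finding AUROC table
#'
#' The packaged fixture of per-finding AUROC point estimates (with their
#' reported half-widths) for the internal-validation, external-validation
#' and end-user experiments, for the comparison reference and the four
#' model variants. Used by [aggregate_mean_auroc()] to reproduce the
#' averaged AUROCs quoted in prose.
#'
#' @return A tibble with columns `experiment`, `model`, `finding`, `auroc`,
#'   `margin`.
#' @export
cxr_table1 <- function() {
  path <- system.file("extdata", "auroc_table.csv", package = "photoreca")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read/write label and score tables
#'
#' CSV dialect: an `image_id` column plus one column per finding.
#'
#' @param path CSV path.
#' @param x A data frame with `image_id` plus finding columns.
#' @return `read_label_table()` returns a tibble; `write_label_table()`
#'   returns `path` invisibly.
#' @export
read_label_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                    stringsAsFactors = FALSE))
}

#' @rdname read_label_table
#' @export
write_label_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Per-finding metrics table for a score matrix
#'
#' Computes AUROC (with bootstrap CI), sensitivity, specificity, F1 and
#' accuracy for every finding column shared between a score table and a
#' label table.
#'
#' @param scores Data frame: `image_id` + per-finding score columns.
#' @param labels Data frame: `image_id` + per-finding binary columns.
#' @param threshold Decision threshold for the binary metrics.
#' @param n_boot Bootstrap resamples for the AUROC CI.
#' @param seed RNG seed.
#' @return A tibble with one row per finding.
#' @export
metrics_table <- function(scores, labels, threshold = 0.5, n_boot = 1000L,
                          seed = 0L) {
  common <- intersect(setdiff(names(scores), "image_id"),
                      setdiff(names(labels), "image_id"))
  if (length(common) == 0) stop("no shared finding columns", call. = FALSE)
  labels <- labels[match(scores$image_id, labels$image_id), , drop = FALSE]
  purrr::imap_dfr(stats::setNames(common, common), function(f, nm) {
    s <- scores[[f]]; y <- labels[[f]]
    if (length(unique(y)) < 2L) {
      return(tibble::tibble(finding = nm, auroc = NA_real_,
                            auroc_ci_low = NA_real_, auroc_ci_high = NA_real_,
                            sensitivity = NA_real_, specificity = NA_real_,
                            f1 = NA_real_, accuracy = mean((s >= threshold) == y)))
    }
    bs <- bootstrap_auroc(s, y, n_boot, seed)
    bm <- binary_metrics(s, y, threshold)
    tibble::tibble(finding = nm, auroc = bs$auroc,
                   auroc_ci_low = bs$ci_low, auroc_ci_high = bs$ci_high,
                   sensitivity = bm$sensitivity, specificity = bm$specificity,
                   f1 = bm$f1, accuracy = bm$accuracy)
  })
}
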