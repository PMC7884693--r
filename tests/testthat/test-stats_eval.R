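test_that("auroc equals the Mann-Whitney pairwise statistic", {
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.8, 0.9, 0.1, 0.2), c(0, 0, 1, 1)), 0)
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  # ties counted one half
  expect_equal(auroc(c(0.5, 0.5), c(0, 1)), 0.5)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "one class")

  # exhaustive pairwise-counting oracle over random small inputs
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 2)  # coarse grid to exercise ties
    expect_equal(auroc(scores, truth), auroc_pair_oracle(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("auroc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  scores <- runif(60)
  truth <- rbinom(60, 1, 0.4)
  ref <- as.numeric(suppressMessages(pROC::auc(truth, scores,
                                               direction = "<")))
  expect_equal(auroc(scores, truth), ref, tolerance = 1e-12)
})

test_that("binary metrics follow confusion-matrix arithmetic", {
  perfect <- binary_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1,
                                  f1 = 1, accuracy = 1))

  allneg <- binary_metrics(rep(0.1, 10), rep(c(1, 0), each = 5))
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)
  expect_equal(allneg$accuracy, 0.5)

  # TP=3, FP=1, FN=1, TN=5
  truth <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  scores <- c(0.9, 0.9, 0.9, 0.1, 0.9, 0.1, 0.1, 0.1, 0.1, 0.1)
  m <- binary_metrics(scores, truth)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$f1, 0.75)
  expect_equal(m$accuracy, 0.8)

  expect_warning(binary_metrics(rep(0.1, 4), rep(0, 4)), "F1 undefined")
})

test_that("bootstrap AUROC is seeded, redraws degenerate samples, and brackets", {
  scores <- c(rep(0.9, 5), rep(0.1, 5))
  truth <- rep(c(1, 0), each = 5)
  b <- bootstrap_auroc(scores, truth, n_boot = 100, seed = 1)
  expect_true(all(b$samples == 1))
  expect_equal(c(b$ci_low, b$ci_high), c(1, 1))

  set.seed(10)
  s2 <- runif(200); y2 <- rbinom(200, 1, 0.3)
  s2[y2 == 1] <- s2[y2 == 1] + 0.3
  b2 <- bootstrap_auroc(s2, y2, n_boot = 500, seed = 2)
  expect_identical(b2$samples,
                   bootstrap_auroc(s2, y2, n_boot = 500, seed = 2)$samples)
  expect_lte(b2$ci_low, b2$auroc)
  expect_gte(b2$ci_high, b2$auroc)
  expect_error(bootstrap_auroc(s2, y2, n_boot = 1), ">= 2")

  # bootstrap mean converges to the point estimate
  b3 <- bootstrap_auroc(s2, y2, n_boot = 5000, seed = 3)
  expect_lt(abs(mean(b3$samples) - b3$auroc), 0.01)
})

test_that("Welch's test matches the textbook formula and its edge cases", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_lt(abs(same$t_statistic), 1e-12)

  eq <- welch_t_test(rep(1, 5), rep(1, 5))
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_warning(out <- welch_t_test(rep(1, 5), rep(2, 5)), "constant")
  expect_equal(out$p_value, 0)

  set.seed(8)
  a <- rnorm(1000, 0.70, 0.01)
  b <- rnorm(1000, 0.75, 0.01)
  expect_lt(welch_t_test(a, b)$p_value, 1e-10)

  set.seed(9)
  x <- rnorm(10); y <- rnorm(10, 0.5)
  got <- welch_t_test(x, y)
  orc <- welch_oracle(x, y)
  expect_equal(got$t_statistic, orc$t, tolerance = 1e-9)
  expect_equal(got$df, orc$df, tolerance = 1e-9)
  expect_equal(got$p_value, orc$p, tolerance = 1e-9)
})

test_that("ICC(A,1) matches the ANOVA oracle and its known orderings", {
  m_same <- matrix(rep(seq(0.1, 0.8, length.out = 8), 3), 8, 3)
  expect_equal(icc_single_absolute(m_same)$icc, 1, tolerance = 1e-12)

  set.seed(12)
  base <- runif(10)
  m_shift <- cbind(base, base + 0.3)
  r <- icc_single_absolute(m_shift)
  expect_lt(r$icc, 1)
  expect_lt(r$icc, icc_consistency_oracle(m_shift))

  set.seed(13)
  m <- matrix(runif(24), 8, 3)
  got <- icc_single_absolute(m)
  expect_equal(got$icc, icc_aov_oracle(m), tolerance = 1e-9)
  expect_lte(got$ci_low, got$icc)
  expect_gte(got$ci_high, got$icc)

  # invariances: common constant shift, subject permutation
  expect_equal(icc_single_absolute(m + 0.2)$icc, got$icc, tolerance = 1e-9)
  expect_equal(icc_single_absolute(m[sample(8), ])$icc, got$icc,
               tolerance = 1e-9)

  expect_error(icc_single_absolute(matrix(c(NA, runif(5)), 3, 2)), "missing")
  expect_error(icc_single_absolute(matrix(1, 1, 3)), "at least 2")
  expect_true(is.na(icc_single_absolute(matrix(1, 5, 3))$icc))
})

test_that("bootstrap comparison wrapper reports a seeded Welch test", {
  set.seed(30)
  y <- rbinom(120, 1, 0.4)
  sa <- runif(120) + 0.4 * y
  sb <- runif(120) + 0.1 * y
  cmp <- compare_bootstrap_auroc(sa, sb, y, n_boot = 200, seed = 5)
  expect_identical(length(cmp$samples_a), 200L)
  expect_lt(cmp$p_value, 0.01)
  expect_gt(cmp$t_statistic, 0)
})

test_that("averaged AUROC reproduces the published table's quoted means", {
  tab <- cxr_table1()
  expect_identical(sort(unique(tab$model)),
                   c("orig", "phot", "reca", "reference", "trns"))
  ext <- tab[tab$experiment == "external", ]
  expect_equal(aggregate_mean_auroc(ext, "phot"), 0.59)
  expect_equal(aggregate_mean_auroc(ext, "trns"), 0.71)
  expect_error(aggregate_mean_auroc(ext[ext$finding != "edema", ], "phot"),
               "edema")

  six <- tibble::tibble(finding = major_findings(), model = "m",
                        auroc = rep(0.7, 6))
  expect_equal(aggregate_mean_auroc(six, "m"), 0.7)
})

test_that("metrics_table evaluates every shared finding column", {
  set.seed(40)
  n <- 80
  labels <- tibble::tibble(image_id = sprintf("i%03d", 1:n),
                           a = rbinom(n, 1, 0.3), b = rbinom(n, 1, 0.5))
  scores <- tibble::tibble(image_id = labels$image_id,
                           a = runif(n) + 0.5 * labels$a,
                           b = runif(n))
  mt <- metrics_table(scores, labels, n_boot = 100, seed = 1)
  expect_identical(nrow(mt), 2L)
  expect_gt(mt$auroc[mt$finding == "a"], 0.7)
  expect_true(all(mt$auroc_ci_low <= mt$auroc_ci_high, na.rm = TRUE))
})
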