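#' Baseline multi-label classifier
#'
#' A deliberately simple stand-in for a deep convolutional network: one
#' ridge-penalized logistic regression per finding (one-versus-all) on
#' `feature_side x feature_side` downsampled pixel intensities. It trains
#' in seconds at a few thousand images, which is all the desk-scale
#' experiment needs -- the recalibration mechanism under study is
#' classifier-agnostic.
#'
#' The returned object fulfils the classifier contract: `fit(images,
#' labels)`, `score(images)` returning an images x findings matrix of
#' probabilities in `[0, 1]`, and optionally `refit(images, labels)` for
#' transfer-style fine-tuning (here: a ridge-penalized additive correction
#' on top of the frozen fitted linear predictor).
#'
#' @param feature_side Downsampling side for the pixel features
#'   (default 32).
#' @param lambda Ridge penalty for the main fit.
#' @param refit_lambda Ridge penalty for the fine-tuning correction
#'   (stronger, keeping the correction small as a fine-tune should).
#' @return A `classifier_contract` object.
#' @export
baseline_classifier <- function(feature_side = 32L, lambda = 0.05,
                                refit_lambda = 0.5) {
  env <- new.env(parent = emptyenv())
  env$models <- NULL

  featurize <- function(images) {
    t(vapply(images, function(im) {
      as.numeric(unclass(resize_to(as_gray_image(im), feature_side)))
    }, numeric(feature_side * feature_side)))
  }

  label_matrix <- function(labels) {
    cols <- intersect(major_findings(), names(labels))
    as.matrix(labels[, cols, drop = FALSE])
  }

  # Fit along a descending lambda path ending at the target penalty (warm
  # starts keep the coordinate descent stable), then always predict at the
  # target.
  fit_one <- function(x, y, lam) {
    if (length(unique(y)) < 2L || min(table(y)) < 2L) {
      return(list(constant = mean(y)))
    }
    lams <- exp(seq(log(lam * 100), log(lam), length.out = 20L))
    list(fit = suppressWarnings(
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = lams, standardize = TRUE)),
      s = lam)
  }

  # Ridge-penalized logistic IRLS with a fixed offset, solved in the row
  # space of x via a thin SVD (exact for the ridge penalty, and bounded:
  # the correction problem is small, n = photograph budget).
  fit_offset_ridge <- function(x, y, offset, lam, maxit = 30L) {
    if (length(unique(y)) < 2L || min(table(y)) < 2L) {
      return(list(constant = mean(y)))
    }
    sv <- svd(x)
    r <- sum(sv$d > max(sv$d) * 1e-10)
    Z <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
    M <- cbind(1, Z)
    pen <- diag(c(0, rep(lam * nrow(x), r)))
    theta <- numeric(r + 1L)
    for (it in seq_len(maxit)) {
      eta <- offset + drop(M %*% theta)
      p <- stats::plogis(eta)
      w <- pmax(p * (1 - p), 1e-6)
      u <- drop(M %*% theta) + (y - p) / w
      new_theta <- solve(crossprod(M, w * M) + pen, crossprod(M, w * u))
      delta <- max(abs(new_theta - theta))
      theta <- drop(new_theta)
      if (delta < 1e-8) break
    }
    beta <- sv$v[, seq_len(r), drop = FALSE] %*% theta[-1]
    list(b0 = theta[1], beta = drop(beta))
  }

  score_one <- function(model, x, offset = NULL) {
    if (!is.null(model$constant)) return(rep(model$constant, nrow(x)))
    if (!is.null(model$beta)) {
      off <- if (is.null(offset)) 0 else offset
      return(stats::plogis(off + model$b0 + drop(x %*% model$beta)))
    }
    stats::plogis(stats::predict(model$fit, x, type = "link",
                                 s = model$s)[, 1])
  }

  # Saturate the frozen linear predictor used as a fine-tuning offset:
  # ridge-logistic base fits can separate the training data, and unbounded
  # offsets destabilize the correction fit without changing the implied
  # probabilities.
  clamp_lp <- function(x) pmin(pmax(x, -5), 5)

  linear_predictor <- function(models, x) {
    vapply(models, function(m) {
      if (!is.null(m$constant)) {
        rep(stats::qlogis(min(max(m$constant, 1e-6), 1 - 1e-6)), nrow(x))
      } else if (!is.null(m$beta)) {
        m$b0 + drop(x %*% m$beta)
      } else {
        stats::predict(m$fit, x, type = "link", s = m$s)[, 1]
      }
    }, numeric(nrow(x)))
  }

  obj <- list(
    descriptor = sprintf(
      "ridge logistic one-vs-all on %dx%d pixels (lambda=%g)",
      feature_side, feature_side, lambda),
    fit = function(images, labels) {
      x <- featurize(images)
      ym <- label_matrix(labels)
      if (nrow(x) != nrow(ym)) {
        stop("classifier contract violation: image count (", nrow(x),
             ") != label rows (", nrow(ym), ")", call. = FALSE)
      }
      env$models <- lapply(seq_len(ncol(ym)), function(j) {
        fit_one(x, ym[, j], lambda)
      })
      names(env$models) <- colnames(ym)
      env$base <- NULL
      invisible(NULL)
    },
    refit = function(images, labels) {
      if (is.null(env$models)) {
        stop("classifier contract violation: refit() before fit()",
             call. = FALSE)
      }
      x <- featurize(images)
      ym <- label_matrix(labels)
      base_lp <- clamp_lp(linear_predictor(env$models, x))
      env$base <- env$models
      env$models <- lapply(seq_len(ncol(ym)), function(j) {
        fit_offset_ridge(x, ym[, j], base_lp[, j], refit_lambda)
      })
      names(env$models) <- colnames(ym)
      invisible(NULL)
    },
    score = function(images) {
      if (is.null(env$models)) {
        stop("classifier contract violation: score() before fit()",
             call. = FALSE)
      }
      x <- featurize(images)
      base_lp <- if (!is.null(env$base)) clamp_lp(linear_predictor(env$base, x))
      out <- vapply(seq_along(env$models), function(j) {
        score_one(env$models[[j]], x,
                  offset = if (!is.null(base_lp)) base_lp[, j])
      }, numeric(nrow(x)))
      out <- matrix(out, nrow = nrow(x),
                    dimnames = list(NULL, names(env$models)))
      out
    },
    clone = function() baseline_classifier(feature_side, lambda, refit_lambda)
  )
  structure(obj, class = "classifier_contract")
}

#' @export
print.classifier_contract <- function(x, ...) {
  cat("<classifier_contract:", x$descriptor, ">\n")
  invisible(x)
}

#' Run the four-model recalibration experiment on synthetic data
#'
#' Desk-scale re-enactment of the four-model design. Clean pseudo-CXRs are
#' generated and split into disjoint train, photograph-budget and test
#' partitions; the capture simulator (with hidden `truth`) produces the
#' "real photographs". Then:
#' \describe{
#'   \item{ORIG}{trained on the clean training images.}
#'   \item{RECA}{trained on the clean training images degraded with the two
#'     configurations calibrated against the photograph budget (one per
#'     similarity objective), doubling the training set.}
#'   \item{TRNS}{ORIG fine-tuned on the photograph budget.}
#'   \item{PHOT}{trained on the photograph budget alone.}
#' }
#' All models are scored on photographs of the held-out test images; ORIG
#' scored on the clean test images is the comparison reference (REF). The
#' per-finding recovery fraction is
#' `(AUROC_RECA - AUROC_ORIG) / (AUROC_REF - AUROC_ORIG)` on those
#' conditions, flagged indeterminate when the reference loss is below
#' 0.01. All inputs to the classifier are histogram-equalized first.
#'
#' @param spec A [synthetic_spec()]; its `n_images` is ignored in favour of
#'   the partition sizes.
#' @param truth A [capture_truth()] describing the hidden capture process.
#' @param classifier A classifier fulfilling the contract of
#'   [baseline_classifier()].
#' @param n_train,n_test Clean training and test partition sizes.
#' @param photo_budget Number of photographs available for calibration and
#'   for TRNS/PHOT training; defaults to 10% of the RECA training budget
#'   (`2 * n_train`).
#' @param configs Optional list with elements `cwssim` and `bhattacharyya`
#'   giving precomputed calibrated configurations; if `NULL` they are
#'   calibrated from the photograph budget by [select_dual_configs()].
#' @param n_calib Number of photographs used for the calibration objective.
#' @param calib_passes Coordinate-descent passes for the in-experiment
#'   calibration (default 1: the harness trades search depth for run time;
#'   standalone [calibrate()] defaults to 2).
#' @param n_boot Bootstrap resamples for the AUROC confidence intervals.
#' @param seed Master seed for the run.
#' @return An `experiment_report`: `metrics` (finding x model x condition
#'   AUROCs with CIs), `recovery` (per-finding recovery fractions),
#'   `configs`, and the sizes/seeds used.
#' @export
run_recalibration_experiment <- function(spec, truth,
                                         classifier = baseline_classifier(),
                                         n_train = 800L, n_test = 400L,
                                         photo_budget = NULL,
                                         configs = NULL, n_calib = 8L,
                                         calib_passes = 1L,
                                         n_boot = 200L, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(truth, "capture_truth"))
  if (is.null(photo_budget)) photo_budget <- ceiling(0.1 * 2 * n_train)
  n_total <- n_train + photo_budget + n_test
  ds <- generate_dataset(synthetic_spec(
    n_images = n_total, side = spec$side,
    finding_prevalences = spec$finding_prevalences, seed = spec$seed))

  idx_train <- seq_len(n_train)
  idx_photo <- n_train + seq_len(photo_budget)
  idx_test <- n_train + photo_budget + seq_len(n_test)
  stopifnot(length(intersect(idx_train, idx_test)) == 0L,
            length(intersect(idx_photo, idx_test)) == 0L)

  capture_seed <- function(i) (truth$seed + 7919L * i) %% 2147483647L
  photos_budget <- purrr::map(idx_photo, function(i) {
    simulate_capture(ds$images[[i]], truth, seed = capture_seed(i))
  })
  photos_test <- purrr::map(idx_test, function(i) {
    simulate_capture(ds$images[[i]], truth, seed = capture_seed(i))
  })

  if (is.null(configs)) {
    calib_n <- min(n_calib, photo_budget)
    configs <- select_dual_configs(
      train_images = ds$images[idx_photo[seq_len(calib_n)]],
      reference_photos = photos_budget[seq_len(calib_n)],
      search = "coordinate", seed = seed, passes = calib_passes,
      fixed_config = degradation_config(seed = seed))
  }

  # recalibration training set: each clean training image degraded under
  # both calibrated configurations (train set doubles)
  base_cw <- config_seed(configs$cwssim)
  base_bh <- config_seed(configs$bhattacharyya)
  aug_images <- c(
    purrr::imap(ds$images[idx_train], function(im, i) {
      degrade(im, configs$cwssim, seed = (base_cw + i) %% 2147483647L)
    }),
    purrr::imap(ds$images[idx_train], function(im, i) {
      degrade(im, configs$bhattacharyya, seed = (base_bh + i) %% 2147483647L)
    })
  )
  aug_labels <- dplyr::bind_rows(ds$labels[idx_train, ], ds$labels[idx_train, ])

  eq <- function(imgs) purrr::map(imgs, equalize_histogram)
  clean_train <- eq(ds$images[idx_train])
  clean_test <- eq(ds$images[idx_test])
  photos_budget <- eq(photos_budget)
  photos_test <- eq(photos_test)
  aug_images <- eq(aug_images)

  labels_train <- ds$labels[idx_train, ]
  labels_photo <- ds$labels[idx_photo, ]
  labels_test <- ds$labels[idx_test, ]

  orig <- classifier$clone(); orig$fit(clean_train, labels_train)
  reca <- classifier$clone(); reca$fit(aug_images, aug_labels)
  phot <- classifier$clone(); phot$fit(photos_budget, labels_photo)
  trns <- classifier$clone()
  trns$fit(clean_train, labels_train)
  if (!is.null(trns$refit)) {
    trns$refit(photos_budget, labels_photo)
  } else {
    trns$fit(photos_budget, labels_photo)
  }

  score_sets <- list(
    REF = list(model = orig, images = clean_test, condition = "clean"),
    ORIG = list(model = orig, images = photos_test, condition = "photo"),
    RECA = list(model = reca, images = photos_test, condition = "photo"),
    TRNS = list(model = trns, images = photos_test, condition = "photo"),
    PHOT = list(model = phot, images = photos_test, condition = "photo")
  )

  metrics <- purrr::imap_dfr(score_sets, function(set, model_name) {
    sc <- set$model$score(set$images)
    purrr::map_dfr(colnames(sc), function(f) {
      y <- labels_test[[f]]
      if (length(unique(y)) < 2L) {
        return(tibble::tibble(finding = f, model = model_name,
                              condition = set$condition, auroc = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_))
      }
      bs <- bootstrap_auroc(sc[, f], y, n_boot = n_boot,
                            seed = (seed + config_seed_str(model_name, f)) %%
                              2147483647L)
      tibble::tibble(finding = f, model = model_name,
                     condition = set$condition, auroc = bs$auroc,
                     ci_low = bs$ci_low, ci_high = bs$ci_high)
    })
  })

  wide <- tidyr::pivot_wider(metrics[, c("finding", "model", "auroc")],
                             names_from = "model", values_from = "auroc")
  recovery <- dplyr::mutate(
    wide,
    loss = .data$REF - .data$ORIG,
    recovery = ifelse(.data$loss > 0.01,
                      (.data$RECA - .data$ORIG) / .data$loss, NA_real_),
    indeterminate = !(.data$loss > 0.01)
  )[, c("finding", "recovery", "indeterminate")]

  structure(
    list(metrics = metrics, recovery = recovery, configs = configs,
         truth = truth,
         sizes = list(n_train = n_train, n_test = n_test,
                      photo_budget = photo_budget, side = spec$side),
         seed = seed, classifier = classifier$descriptor),
    class = "experiment_report"
  )
}

# Small deterministic per-(model, finding) seed offset.
config_seed_str <- function(...) {
  s <- paste(..., collapse = "|")
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 1000003
  as.integer(h)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf(
    "<experiment_report: n_train=%d, n_test=%d, photo_budget=%d, seed=%d>\n",
    x$sizes$n_train, x$sizes$n_test, x$sizes$photo_budget, x$seed))
  means <- dplyr::summarise(
    dplyr::group_by(x$metrics, .data$model, .data$condition),
    mean_auroc = mean(.data$auroc, na.rm = TRUE), .groups = "drop")
  print(means)
  cat(sprintf("mean recovery fraction: %.3f\n",
              mean(x$recovery$recovery, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.experiment_report <- function(x, ...) {
  tibble::as_tibble(x$metrics)
}

#' @export
glance.experiment_report <- function(x, ...) {
  means <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(x$metrics, .data$model),
                     mean_auroc = mean(.data$auroc, na.rm = TRUE),
                     .groups = "drop"),
    names_from = "model", values_from = "mean_auroc", names_prefix = "mean_")
  dplyr::bind_cols(means, tibble::tibble(
    mean_recovery = mean(x$recovery$recovery, na.rm = TRUE),
    n_train = x$sizes$n_train, n_test = x$sizes$n_test, seed = x$seed))
}

#' Plot an experiment report
#'
#' Dot-and-interval plot of per-finding AUROCs by model.
#'
#' @param object An `experiment_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_report <- function(object, ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$finding, y = .data$auroc,
                               colour = .data$model, shape = .data$condition)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "AUROC", colour = "model",
                  shape = "test condition") +
    ggplot2::theme_minimal()
}

#' Serialize an experiment report to JSON
#'
#' @param x An `experiment_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_experiment_report <- function(x, path) {
  stopifnot(inherits(x, "experiment_report"))
  out <- list(metrics = x$metrics, recovery = x$recovery,
              configs = lapply(x$configs, unclass),
              sizes = x$sizes, seed = x$seed, classifier = x$classifier)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
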