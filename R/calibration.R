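#' Build an evenly spaced search grid over hyperparameter ranges
#'
#' Each parameter gets `n_steps` evenly spaced values including both range
#' endpoints; a single step collapses to the range midpoint. The default
#' ranges are the ten calibration ranges of [param_ranges()].
#'
#' @param ranges Named list of `c(low, high)` pairs.
#' @param n_steps Values per parameter (>= 1).
#' @return A `parameter_grid`: named list of value vectors plus
#'   `total_points`, the full-grid size.
#' @export
build_grid <- function(ranges = param_ranges(), n_steps = 3L) {
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) {
    stop("`n_steps` must be >= 1", call. = FALSE)
  }
  values <- lapply(ranges, function(r) {
    if (length(r) != 2L || r[1] > r[2]) {
      stop("each range must be a c(low, high) pair with low <= high",
           call. = FALSE)
    }
    if (n_steps == 1L) mean(r) else seq(r[1], r[2], length.out = n_steps)
  })
  structure(list(values = values,
                 total_points = prod(vapply(values, length, integer(1)))),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("<parameter_grid: %d parameters, %g full-grid points>\n",
              length(x$values), x$total_points))
  invisible(x)
}

# Override fields of a degradation_config, revalidating.
update_config <- function(cfg, overrides) {
  fields <- unclass(cfg)
  for (nm in names(overrides)) fields[[nm]] <- overrides[[nm]]
  do.call(degradation_config, fields)
}

# Similarity objective: degrade every training image under `cfg` with a
# deterministic config-hash-derived seed (so the objective is a pure
# function of the config), then score against the references.
config_objective <- function(cfg, train_images, references, metric,
                             levels = 4L) {
  base <- config_seed(cfg)
  degraded <- purrr::imap(train_images, function(img, i) {
    degrade(img, cfg, seed = (base + i) %% 2147483647L)
  })
  pairing <- if (length(degraded) == length(references)) "matched" else "cross"
  rep <- compare_sets(degraded, references, pairing = pairing,
                      metrics = metric, levels = levels)
  if (metric == "cwssim") rep$mean_cwssim else rep$mean_bhattacharyya
}

#' Calibrate the degradation simulator against reference photographs
#'
#' Searches the hyperparameter space so that degraded training images score
#' as photograph-like as possible against a small reference photograph set.
#' Three selection strategies are supported: `"similarity"` (the search
#' proper), `"random"` (each parameter drawn uniformly from its range), and
#' `"manual"` (a supplied configuration passed through unchanged). The
#' similarity strategy supports an exhaustive `full_grid` search or
#' `coordinate` descent (two passes over the parameters, starting from
#' range midpoints).
#'
#' @param train_images List of clean [gray_image()]s to degrade.
#' @param reference_photos List of reference photograph [gray_image()]s.
#'   When the two lists have equal length they are compared pairwise
#'   (matched by underlying image), otherwise each degraded image is scored
#'   against its most favourable reference.
#' @param metric `"cwssim"` (maximized) or `"bhattacharyya"` (minimized).
#' @param strategy `"similarity"`, `"random"`, or `"manual"`.
#' @param search `"coordinate"` or `"full_grid"` (similarity strategy only).
#' @param ranges Named list of ranges to search; parameters not listed stay
#'   at their `fixed_config` values.
#' @param n_steps Grid values per searched parameter.
#' @param fixed_config Base [degradation_config()] supplying all
#'   non-searched fields.
#' @param manual_config Configuration returned unchanged when
#'   `strategy = "manual"`.
#' @param passes Coordinate-descent passes (default 2).
#' @param seed RNG seed (random strategy and tie-breaking are seeded).
#' @return A `calibration_result` with the searched evaluations (a tibble),
#'   `best_config`, and `best_objective`.
#' @export
calibrate <- function(train_images, reference_photos,
                      metric = c("cwssim", "bhattacharyya"),
                      strategy = c("similarity", "random", "manual"),
                      search = c("coordinate", "full_grid"),
                      ranges = param_ranges(), n_steps = 3L,
                      fixed_config = degradation_config(),
                      manual_config = NULL, passes = 2L, seed = 0L) {
  metric <- match.arg(metric)
  strategy <- match.arg(strategy)
  search <- match.arg(search)
  if (strategy != "manual" &&
      (length(train_images) == 0 || length(reference_photos) == 0)) {
    stop("need at least one training image and one reference photo",
         call. = FALSE)
  }
  better <- if (metric == "cwssim") `>` else `<`
  obj <- function(cfg) config_objective(cfg, train_images, reference_photos,
                                        metric)

  if (strategy == "manual") {
    if (is.null(manual_config)) {
      stop("strategy 'manual' requires `manual_config`", call. = FALSE)
    }
    return(new_calibration_result(
      strategy, metric, evaluations = tibble::tibble(),
      best_config = manual_config, best_objective = NA_real_,
      n_reference_photos = length(reference_photos), seed = seed))
  }

  if (strategy == "random") {
    cfg <- withr::with_seed(as.integer(seed), {
      draws <- lapply(ranges, function(r) stats::runif(1, r[1], r[2]))
      update_config(fixed_config, draws)
    })
    val <- obj(cfg)
    evals <- tibble::as_tibble(c(unclass(cfg)[names(ranges)],
                                 list(objective = val)))
    return(new_calibration_result(strategy, metric, evals, cfg, val,
                                  length(reference_photos), seed))
  }

  grid <- build_grid(ranges, n_steps)
  evals <- list()
  record <- function(cfg, val) {
    evals[[length(evals) + 1L]] <<-
      c(unclass(cfg)[names(ranges)], list(objective = val))
  }

  if (search == "full_grid") {
    points <- do.call(expand.grid, c(grid$values, KEEP.OUT.ATTRS = FALSE))
    best_cfg <- NULL; best_val <- NULL
    for (i in seq_len(nrow(points))) {
      cfg <- update_config(fixed_config, as.list(points[i, , drop = FALSE]))
      val <- obj(cfg)
      record(cfg, val)
      if (is.null(best_val) || better(val, best_val)) {
        best_val <- val; best_cfg <- cfg
      }
    }
  } else {
    current <- lapply(grid$values, function(v) v[(length(v) + 1L) %/% 2L])
    best_cfg <- update_config(fixed_config, current)
    best_val <- obj(best_cfg)
    record(best_cfg, best_val)
    for (pass in seq_len(passes)) {
      for (p in names(grid$values)) {
        for (v in grid$values[[p]]) {
          if (isTRUE(all.equal(v, current[[p]]))) next
          cand <- current
          cand[[p]] <- v
          cfg <- update_config(fixed_config, cand)
          val <- obj(cfg)
          record(cfg, val)
          if (better(val, best_val)) {
            best_val <- val; best_cfg <- cfg; current <- cand
          }
        }
      }
    }
  }
  new_calibration_result(strategy, metric, dplyr::bind_rows(evals),
                         best_cfg, best_val, length(reference_photos), seed)
}

new_calibration_result <- function(strategy, metric, evaluations, best_config,
                                   best_objective, n_reference_photos, seed) {
  structure(
    list(strategy = strategy, metric = metric, evaluations = evaluations,
         best_config = best_config, best_objective = best_objective,
         n_reference_photos = n_reference_photos, seed = seed),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result: strategy %s, metric %s, %d evaluations, best objective %s>\n",
    x$strategy, x$metric,
    if (is.data.frame(x$evaluations)) nrow(x$evaluations) else 0L,
    format(x$best_objective, digits = 5)))
  invisible(x)
}

#' @export
tidy.calibration_result <- function(x, ...) {
  tibble::as_tibble(x$evaluations)
}

#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy, metric = x$metric,
    n_evaluations = if (is.data.frame(x$evaluations)) nrow(x$evaluations)
                    else 0L,
    best_objective = x$best_objective,
    n_reference_photos = x$n_reference_photos, seed = x$seed
  )
}

#' Serialize a calibration result to JSON and back
#'
#' @param x A `calibration_result`.
#' @param path File path.
#' @return `read_calibration()` returns the `calibration_result`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(x, path) {
  stopifnot(inherits(x, "calibration_result"))
  out <- list(strategy = x$strategy, metric = x$metric,
              evaluations = x$evaluations,
              best_config = unclass(x$best_config),
              best_objective = x$best_objective,
              n_reference_photos = x$n_reference_photos, seed = x$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_calibration_result(
    x$strategy, x$metric, tibble::as_tibble(x$evaluations),
    do.call(degradation_config, as.list(x$best_config)),
    x$best_objective, x$n_reference_photos, x$seed
  )
}

#' Select the pair of calibrated configurations
#'
#' Runs two independent similarity calibrations -- one per objective -- and
#' returns both selected configurations. The recalibration training set is
#' augmented with both, one emphasising structural (CW-SSIM) agreement and
#' one intensity-distribution (Bhattacharyya) agreement.
#'
#' @inheritParams calibrate
#' @param ... Passed on to [calibrate()].
#' @return A list of two [degradation_config()]s named `cwssim` and
#'   `bhattacharyya`.
#' @export
select_dual_configs <- function(train_images, reference_photos,
                                search = c("coordinate", "full_grid"),
                                seed = 0L, ...) {
  search <- match.arg(search)
  list(
    cwssim = calibrate(train_images, reference_photos, metric = "cwssim",
                       strategy = "similarity", search = search,
                       seed = seed, ...)$best_config,
    bhattacharyya = calibrate(train_images, reference_photos,
                              metric = "bhattacharyya",
                              strategy = "similarity", search = search,
                              seed = seed, ...)$best_config
  )
}
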