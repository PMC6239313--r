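#' F-score with recall weighted twice as heavily as precision
#'
#' `F2 = 5 * R * P / (4 * P + R)`, the F-beta score at beta = 2. Used to
#' judge detection output where a missed organism is costlier than a
#' false alarm (false positives are cheap to dismiss in grid review).
#' Defined as 0 when recall and precision are both 0.
#'
#' @param recall,precision Fractions in `[0, 1]` (vectorised).
#' @return F2 fraction in `[0, 1]`.
#' @examples
#' f2_score(0.917, 0.505)  # 0.788...
#' @export
f2_score <- function(recall, precision) {
  if (any(recall < 0 | recall > 1 | precision < 0 | precision > 1,
          na.rm = TRUE)) {
    abort("`recall` and `precision` must lie in [0, 1].")
  }
  out <- ifelse(recall == 0 & precision == 0, 0,
                5 * recall * precision / (4 * precision + recall))
  unname(out)
}

#' Region-level detection evaluation
#'
#' Counts detections the way grid review experiences them, on two sides:
#' object-side, an object of interest (OOI) is found (`tp_theta`) if its
#' ground-truth centre lies inside some detected region, otherwise missed
#' (`fn_theta`); region-side, a detected region is a true positive
#' (`tp_rho`) if it contains at least one OOI centre, else a false
#' positive (`fp_rho`). One region containing k OOI contributes k to
#' `tp_theta` but only 1 to `tp_rho`. Then
#' `recall = tp_theta / (tp_theta + fn_theta)` and
#' `precision = tp_rho / (tp_rho + fp_rho)`.
#'
#' @param regions Detected regions: a tibble with `image_id` and either a
#'   square box (`x`, `y`, `edge`) or a circle (`cx`, `cy`, `radius`).
#' @param truth Ground truth: tibble with `image_id`, `cx`, `cy` (object
#'   centres; a `radius`, if present, is ignored under the default rule).
#' @param rule Containment rule: `"center"` (default; the OOI centre must
#'   lie inside the region) or `"overlap"` (the truth circle need only
#'   intersect the region).
#' @return A `detection_eval` object with the four counts, `recall`,
#'   `precision`, `f2` and `precision_defined` (FALSE when there are no
#'   regions, in which case precision is reported as 0).
#' @export
match_detections <- function(regions, truth, rule = c("center", "overlap")) {
  rule <- match.arg(rule)
  if (anyNA(regions$image_id) || anyNA(truth$image_id)) {
    abort("`regions` and `truth` must have non-missing image ids.")
  }
  is_box <- all(c("x", "y", "edge") %in% names(regions))
  if (!is_box && !all(c("cx", "cy", "radius") %in% names(regions))) {
    abort("`regions` needs box columns (x, y, edge) or circle columns (cx, cy, radius).")
  }
  slack <- if (rule == "overlap" && "radius" %in% names(truth)) {
    truth$radius
  } else {
    rep(0, nrow(truth))
  }
  region_hit <- logical(nrow(regions))
  truth_hit <- logical(nrow(truth))
  for (i in seq_len(nrow(regions))) {
    same <- which(truth$image_id == regions$image_id[i])
    if (length(same) == 0L) next
    if (is_box) {
      x0 <- regions$x[i]
      y0 <- regions$y[i]
      e <- regions$edge[i]
      hit <- truth$cx[same] >= x0 - slack[same] &
        truth$cx[same] <= x0 + e - 1 + slack[same] &
        truth$cy[same] >= y0 - slack[same] &
        truth$cy[same] <= y0 + e - 1 + slack[same]
    } else {
      d <- sqrt((truth$cx[same] - regions$cx[i])^2 +
                  (truth$cy[same] - regions$cy[i])^2)
      hit <- d <= regions$radius[i] + slack[same]
    }
    region_hit[i] <- any(hit)
    truth_hit[same[hit]] <- TRUE
  }
  tp_theta <- sum(truth_hit)
  fn_theta <- sum(!truth_hit)
  tp_rho <- sum(region_hit)
  fp_rho <- sum(!region_hit)
  recall <- if (tp_theta + fn_theta > 0) tp_theta / (tp_theta + fn_theta) else 0
  precision_defined <- (tp_rho + fp_rho) > 0
  precision <- if (precision_defined) tp_rho / (tp_rho + fp_rho) else 0
  structure(
    list(tp_theta = tp_theta, fn_theta = fn_theta, tp_rho = tp_rho,
         fp_rho = fp_rho, recall = recall, precision = precision,
         f2 = f2_score(recall, precision),
         precision_defined = precision_defined, rule = rule),
    class = "detection_eval"
  )
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf(
    "<detection_eval> recall %.1f%% (%d/%d OOI), precision %.1f%% (%d/%d regions), F2 %.1f%%\n",
    100 * x$recall, x$tp_theta, x$tp_theta + x$fn_theta, 100 * x$precision,
    x$tp_rho, x$tp_rho + x$fp_rho, 100 * x$f2))
  if (!x$precision_defined) cat("  (no regions: precision reported as 0)\n")
  invisible(x)
}

#' @export
tidy.detection_eval <- function(x, ...) {
  tibble(
    metric = c("tp_theta", "fn_theta", "tp_rho", "fp_rho", "recall",
               "precision", "f2"),
    value = c(x$tp_theta, x$fn_theta, x$tp_rho, x$fp_rho, x$recall,
              x$precision, x$f2)
  )
}

#' @export
glance.detection_eval <- function(x, ...) {
  tibble(tp_theta = x$tp_theta, fn_theta = x$fn_theta, tp_rho = x$tp_rho,
         fp_rho = x$fp_rho, recall = x$recall, precision = x$precision,
         f2 = x$f2, precision_defined = x$precision_defined)
}

#' Annotation-time cost model
#'
#' Parameters of the two annotation-time lines: assisted annotation costs
#' a constant setup (building and reviewing the training set for a fixed
#' number of training images) plus a per-image candidate-review rate,
#' while fully manual annotation costs a per-image rate only. The defaults
#' are the published fits: review 18.34 s/image, setup 12327 s, manual
#' 89.27 s/image.
#'
#' @param review_rate Candidate review time, s/image.
#' @param setup_cost Constant preparation time, s.
#' @param trad_rate Fully manual annotation time, s/image.
#' @return A `time_model` object.
#' @export
time_model_params <- function(review_rate = 18.34, setup_cost = 12327,
                              trad_rate = 89.27) {
  assert_scalar_number(review_rate, "review_rate", min = 0)
  assert_scalar_number(setup_cost, "setup_cost", min = 0)
  assert_scalar_number(trad_rate, "trad_rate", min = 0)
  structure(list(review_rate = review_rate, setup_cost = setup_cost,
                 trad_rate = trad_rate),
            class = "time_model")
}

#' @export
print.time_model <- function(x, ...) {
  cat(sprintf("<time_model> assisted: %.2f s/image + %.0f s; manual: %.2f s/image\n",
              x$review_rate, x$setup_cost, x$trad_rate))
  invisible(x)
}

#' Fit the time model from logged annotation sessions
#'
#' Recomputes the cost-model rates from per-dataset session logs instead
#' of taking them as constants. Expected columns of `sessions`: `dataset`;
#' `filter_min`, `refine_min` (Stage II durations in minutes for
#' `n_training_images` images); `tiles_per_image` (1 unless images were
#' tiled; rates measured per tile are extrapolated by this factor);
#' `review_min` (candidate review duration for `n_validation_images`
#' images); `trad_s_per_image` (fully manual rate). Per-dataset rates are
#' averaged unweighted; the setup cost is the mean filter+refine rate
#' times `training_images`.
#'
#' @param sessions Session tibble (see
#'   `system.file("extdata", "annotation_sessions.csv", package = "benthoscan")`
#'   for the published sessions).
#' @param training_images Number of images annotated during setup
#'   (default 500).
#' @return A `time_model` with attribute `"per_dataset"` (tibble of the
#'   per-dataset rates).
#' @export
fit_time_model <- function(sessions, training_images = 500L) {
  prep <- (sessions$filter_min + sessions$refine_min) * 60 /
    sessions$n_training_images * sessions$tiles_per_image
  review <- sessions$review_min * 60 / sessions$n_validation_images *
    sessions$tiles_per_image
  params <- time_model_params(
    review_rate = mean(review),
    setup_cost = mean(prep) * training_images,
    trad_rate = mean(sessions$trad_s_per_image)
  )
  attr(params, "per_dataset") <- tibble(
    dataset = sessions$dataset,
    prep_s_per_image = prep,
    review_s_per_image = review,
    trad_s_per_image = sessions$trad_s_per_image
  )
  params
}

#' Annotation time as a function of dataset size
#'
#' `tau_maia(n)` is the assisted-annotation time
#' `review_rate * n + setup_cost`; `tau_trad(n)` is the fully manual time
#' `trad_rate * n`. Both in seconds, vectorised over `n`.
#'
#' @param n Number of images (>= 0).
#' @param params A [time_model_params()].
#' @return Seconds.
#' @export
tau_maia <- function(n, params = time_model_params()) {
  if (any(n < 0)) abort("`n` must be nonnegative.")
  params$review_rate * n + params$setup_cost
}

#' @rdname tau_maia
#' @export
tau_trad <- function(n, params = time_model_params()) {
  if (any(n < 0)) abort("`n` must be nonnegative.")
  params$trad_rate * n
}

#' Speed-up and break-even point of assisted annotation
#'
#' The speed-up at dataset size `n` is `tau_trad(n) / tau_maia(n)`; the
#' break-even size is the exact crossover
#' `n* = setup_cost / (trad_rate - review_rate)`, beyond which assisted
#' annotation is faster. With the default parameters the speed-up at 550
#' images is 2.19 and the crossover sits just below 174 images.
#'
#' @param params A [time_model_params()].
#' @return List with `speedup` (a function of `n`), `breakeven` (`n*`;
#'   `Inf` with a warning when the manual rate does not exceed the review
#'   rate, in which case there is no crossover) and `crossover_exists`.
#' @export
speedup_and_breakeven <- function(params = time_model_params()) {
  if (params$trad_rate <= params$review_rate) {
    warn("Manual rate does not exceed the review rate: no crossover.")
    breakeven <- Inf
    exists <- FALSE
  } else {
    breakeven <- params$setup_cost / (params$trad_rate - params$review_rate)
    exists <- TRUE
  }
  list(
    speedup = function(n) tau_trad(n, params) / tau_maia(n, params),
    breakeven = breakeven,
    crossover_exists = exists
  )
}

#' @rdname speedup_and_breakeven
#' @param n Dataset size in images.
#' @export
annotation_speedup <- function(n, params = time_model_params()) {
  tau_trad(n, params) / tau_maia(n, params)
}

#' Time-model curves as a tibble / plot
#'
#' @param params A [time_model_params()].
#' @param n_max Largest dataset size shown.
#' @param by Step between evaluated sizes.
#' @return `time_model_curves()`: tibble of `(n, tau_assisted, tau_manual)`;
#'   `plot_time_model()`: a ggplot with the crossover marked.
#' @export
time_model_curves <- function(params = time_model_params(), n_max = 1000L,
                              by = 10L) {
  n <- seq(0L, n_max, by = by)
  tibble(n = n, tau_assisted = tau_maia(n, params),
         tau_manual = tau_trad(n, params))
}

#' @rdname time_model_curves
#' @export
plot_time_model <- function(params = time_model_params(), n_max = 1000L) {
  df <- tidyr::pivot_longer(time_model_curves(params, n_max),
                            -"n", names_to = "method",
                            values_to = "seconds")
  sb <- speedup_and_breakeven(params)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$seconds,
                                        colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "images annotated", y = "total time (s)") +
    ggplot2::theme_minimal()
  if (sb$crossover_exists) {
    p <- p + ggplot2::geom_vline(xintercept = sb$breakeven,
                                 linetype = "dashed")
  }
  p
}

#' Grid search over novelty-detection parameters
#'
#' Runs the unsupervised detection stage end-to-end for every combination
#' of cluster count `K`, patch edge and compression factor, evaluates the
#' resulting proposals against ground truth and tabulates
#' recall/precision/F2. The default grid is
#' `K in {1, 5, 10, 50, 100} x patch_edge in {29, 39} x compression in
#' {0.1, 0.2}`; pass a smaller grid (and a reduced `config`) for
#' desk-scale experiments.
#'
#' @param manifest Manifest tibble.
#' @param truth Ground-truth circle tibble.
#' @param grid Tibble with columns `K`, `patch_edge`, `compression`.
#' @param config Base [aen_config()]; `patch_edge`/`compression` are
#'   overridden per grid row.
#' @param seed Shared seed for every triplet.
#' @param loader Image loader.
#' @param ... Passed to [run_stage1()].
#' @return Tibble: one row per triplet with `recall`, `precision`, `f2`,
#'   `n_proposals`.
#' @export
parameter_search <- function(manifest, truth,
                             grid = tidyr::expand_grid(
                               K = c(1L, 5L, 10L, 50L, 100L),
                               patch_edge = c(29L, 39L),
                               compression = c(0.1, 0.2)),
                             config = aen_config(), seed = 1L,
                             loader = load_image, ...) {
  purrr::pmap_dfr(grid, function(K, patch_edge, compression) {
    cfg <- utils::modifyList(unclass(config),
                             list(patch_edge = as.integer(patch_edge),
                                  compression = compression, seed = seed))
    cfg <- do.call(aen_config, cfg[c(
      "patch_edge", "compression", "learning_rate", "epochs", "minibatch",
      "n_train_patches", "seed", "slice_rows")])
    res <- tryCatch(
      run_stage1(manifest, config = cfg, K = K, seed = seed,
                 loader = loader, ...),
      error = function(e) {
        abort(sprintf(
          "Stage failure at triplet (K = %s, patch_edge = %s, compression = %s): %s",
          K, patch_edge, compression, conditionMessage(e)))
      }
    )
    ev <- match_detections(res$proposals, truth)
    tibble(K = K, patch_edge = patch_edge, compression = compression,
           recall = ev$recall, precision = ev$precision, f2 = ev$f2,
           n_proposals = nrow(res$proposals))
  })
}
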