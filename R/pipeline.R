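#' Run unsupervised novelty detection end-to-end
#'
#' The full first stage: cluster the dataset's images by background
#' appearance, train one data-driven background model per cluster, apply
#' each model convolutionally to its cluster's images, dilate the novelty
#' maps, derive the per-cluster threshold (mean of the maps' 99th
#' percentiles), extract connected interesting regions as square training
#' proposals and rank them by novelty score across the dataset.
#'
#' @param manifest Manifest tibble.
#' @param config An [aen_config()]; its `seed` is combined with the
#'   cluster id so each cluster trains on its own reproducible stream.
#' @param K Number of background clusters (5 is the published default for
#'   real surveys; match the number of distinct sediment types when it is
#'   known).
#' @param seed Seed for the clustering restarts.
#' @param stride Convolution stride (default 2).
#' @param percentile Threshold percentile (default 0.99).
#' @param min_edge Minimum proposal edge in pixels (default 30).
#' @param dilation_edge Dilation kernel edge; defaults to the patch edge.
#' @param keep_maps Keep the dilated novelty maps in the result (memory
#'   permitting) — useful for inspecting score separation.
#' @param loader Image loader.
#' @return A `stage1_result` list: ranked `proposals`, `thresholds`
#'   (tibble of `cluster_id`, `t_k`), the clustered `manifest`, the
#'   `dbms` (one per cluster), the cluster `model`, `config`, and
#'   optionally `maps`.
#' @export
run_stage1 <- function(manifest, config = aen_config(), K = 5L, seed = 1L,
                       stride = 2L, percentile = 0.99, min_edge = 30L,
                       dilation_edge = NULL, keep_maps = FALSE,
                       loader = load_image) {
  clustered <- cluster_images(manifest, K = K, seed = seed, loader = loader)
  manifest <- clustered$manifest
  dbms <- vector("list", K)
  proposals <- list()
  thresholds <- vector("list", K)
  maps_out <- if (keep_maps) list() else NULL
  for (k in seq_len(K)) {
    cfg_k <- unclass(config)
    cfg_k$seed <- config$seed + k - 1L
    cfg_k <- do.call(aen_config, cfg_k[c(
      "patch_edge", "compression", "learning_rate", "epochs", "minibatch",
      "n_train_patches", "seed", "slice_rows")])
    dbms[[k]] <- train_dbm(manifest, cfg_k, cluster_id = k, loader = loader)
    in_k <- manifest[manifest$cluster_id == k, , drop = FALSE]
    maps <- lapply(seq_len(nrow(in_k)), function(i) {
      nm <- apply_dbm(loader(in_k$path[i]), dbms[[k]], stride = stride,
                      image_id = in_k$id[i])
      dilate_novelty_map(nm, dilation_edge %||% config$patch_edge)
    })
    t_k <- compute_threshold(maps, prob = percentile)
    thresholds[[k]] <- tibble(cluster_id = k, t_k = t_k)
    proposals <- c(proposals, lapply(maps, propose_regions, threshold = t_k,
                                     min_edge = min_edge))
    if (keep_maps) maps_out <- c(maps_out, maps)
  }
  structure(
    list(
      proposals = rank_proposals(dplyr::bind_rows(proposals)),
      thresholds = dplyr::bind_rows(thresholds),
      manifest = manifest,
      dbms = dbms,
      model = clustered$model,
      config = config,
      maps = maps_out
    ),
    class = "stage1_result"
  )
}

#' @export
print.stage1_result <- function(x, ...) {
  cat(sprintf(
    "<stage1_result> %d image(s), %d cluster(s), %d proposal(s)\n",
    nrow(x$manifest), nrow(x$thresholds), nrow(x$proposals)))
  invisible(x)
}

#' Evaluate stage-one proposals against ground truth
#'
#' @param result A `stage1_result` (or a proposal tibble).
#' @param truth Ground-truth circle tibble.
#' @param ... Passed to [match_detections()].
#' @return A `detection_eval`.
#' @export
evaluate_stage1 <- function(result, truth, ...) {
  proposals <- if (inherits(result, "stage1_result")) {
    result$proposals
  } else {
    result
  }
  match_detections(proposals, truth, ...)
}

#' Novelty-score separation between objects and background
#'
#' Diagnostic for generated fixtures: the ratio of the mean novelty value
#' over planted-object pixels (inside the ground-truth circles) to the
#' mean over all remaining pixels. Values well above 1 mean the
#' background model flags the planted objects.
#'
#' @param maps List of (dilated) `novelty_map`s.
#' @param truth Ground-truth circle tibble.
#' @return List with `object_mean`, `background_mean`, `ratio`.
#' @export
novelty_separation <- function(maps, truth) {
  obj_sum <- 0; obj_n <- 0; bg_sum <- 0; bg_n <- 0
  for (nm in maps) {
    v <- nm$values
    H <- nrow(v); W <- ncol(v)
    circles <- truth[truth$image_id == nm$image_id, , drop = FALSE]
    inside <- matrix(FALSE, H, W)
    if (nrow(circles) > 0) {
      xs <- matrix(rep(0:(W - 1), each = H), H, W)
      ys <- matrix(rep(0:(H - 1), W), H, W)
      for (i in seq_len(nrow(circles))) {
        inside <- inside | ((xs - circles$cx[i])^2 + (ys - circles$cy[i])^2
                            <= circles$radius[i]^2)
      }
    }
    obj_sum <- obj_sum + sum(v[inside]); obj_n <- obj_n + sum(inside)
    bg_sum <- bg_sum + sum(v[!inside]); bg_n <- bg_n + sum(!inside)
  }
  object_mean <- if (obj_n > 0) obj_sum / obj_n else NA_real_
  background_mean <- if (bg_n > 0) bg_sum / bg_n else NA_real_
  list(object_mean = object_mean, background_mean = background_mean,
       ratio = object_mean / background_mean)
}
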