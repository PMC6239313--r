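#' Novelty threshold of an image cluster
#'
#' The segmentation threshold of a cluster is the mean over its images of
#' the 99th percentile of each image's (dilated) novelty map,
#' `t_k = mean_i P99(N_i)`. Percentiles use linear interpolation between
#' order statistics (`stats::quantile()` type 7).
#'
#' @param maps A list of `novelty_map` objects (one image cluster), or a
#'   single map.
#' @param prob Percentile as a probability (default 0.99).
#' @return Scalar threshold `t_k`.
#' @export
compute_threshold <- function(maps, prob = 0.99) {
  if (inherits(maps, "novelty_map")) maps <- list(maps)
  if (length(maps) == 0L) {
    abort("Cannot compute a threshold for an empty cluster.")
  }
  mean(vapply(maps, function(nm) {
    unname(quantile(nm$values, probs = prob, type = 7, names = FALSE))
  }, numeric(1)))
}

#' Threshold a novelty map into a binary segmentation
#'
#' Marks as "interesting" every pixel whose (dilated) novelty value
#' strictly exceeds the cluster threshold.
#'
#' @param nm A `novelty_map` (normally dilated first, see
#'   [dilate_novelty_map()]).
#' @param threshold Scalar threshold `t_k`.
#' @return Logical `H x W` matrix.
#' @export
segment_novelty_map <- function(nm, threshold) {
  assert_scalar_number(threshold, "threshold")
  nm$values > threshold
}

#' Label connected interesting regions
#'
#' 8-connected component labelling of a binary mask. Labels are assigned
#' deterministically in row-major discovery order (scanning y, then x);
#' background pixels get 0.
#'
#' @param mask Logical `H x W` matrix.
#' @return Integer `H x W` label matrix; `max()` of it is the region count.
#' @export
extract_regions <- function(mask) {
  if (!is.matrix(mask)) abort("`mask` must be a logical matrix.")
  storage.mode(mask) <- "logical"
  cpp_label_components(mask)
}

#' Turn labelled regions into ranked square training proposals
#'
#' Each connected interesting region becomes one square training proposal:
#' the minimum square bounding box of the region, centred on the tight
#' bounding box's centre and expanded to at least `min_edge` pixels
#' (30 by default, so small regions still yield a usable crop). Boxes that
#' would overflow the image are shifted inward, so every proposal is an
#' exactly square in-bounds crop. The proposal's novelty score `eta` is
#' the sum of the region's novelty values.
#'
#' @param nm The (dilated) `novelty_map` the mask came from.
#' @param labels Integer label matrix from [extract_regions()] (or a
#'   logical mask, which is labelled first).
#' @param min_edge Minimum box edge in pixels (default 30).
#' @return Tibble with columns `image_id`, `x`, `y` (0-based top-left
#'   corner), `edge`, `score`, `region_id`.
#' @export
extract_proposals <- function(nm, labels, min_edge = 30L) {
  min_edge <- assert_count(min_edge, "min_edge")
  if (is.logical(labels)) labels <- extract_regions(labels)
  H <- nrow(labels)
  W <- ncol(labels)
  n <- max(labels)
  if (n == 0L) {
    return(tibble(image_id = character(), x = integer(), y = integer(),
                  edge = integer(), score = numeric(),
                  region_id = integer()))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  px <- (idx - 1L) %/% H            # 0-based column (x)
  py <- (idx - 1L) %% H             # 0-based row (y)
  labf <- factor(lab, levels = seq_len(n))   # keep numeric region order
  score <- as.numeric(rowsum(nm$values[idx], lab)[, 1L])
  xmin <- tapply(px, labf, min)
  xmax <- tapply(px, labf, max)
  ymin <- tapply(py, labf, min)
  ymax <- tapply(py, labf, max)
  edge <- pmax(min_edge, xmax - xmin + 1L, ymax - ymin + 1L)
  edge <- pmin(edge, W, H)          # degenerate small images only
  x <- floor((xmin + xmax + 1L - edge) / 2)
  y <- floor((ymin + ymax + 1L - edge) / 2)
  x <- pmin(pmax(x, 0L), W - edge)  # shift inward instead of truncating
  y <- pmin(pmax(y, 0L), H - edge)
  tibble(
    image_id = nm$image_id,
    x = as.integer(x), y = as.integer(y), edge = as.integer(edge),
    score = score,
    region_id = seq_len(n)
  )
}

#' Rank training proposals by novelty score
#'
#' Stable descending sort on the score `eta`; ties are broken by
#' `(image_id, region_id)` so the ranking is deterministic. This is the
#' order in which proposals are presented for manual review.
#'
#' @param proposals Proposal tibble (see [extract_proposals()]).
#' @return The same tibble, reordered, with a `rank` column prepended.
#' @export
rank_proposals <- function(proposals) {
  out <- dplyr::arrange(proposals, dplyr::desc(.data$score),
                        .data$image_id, .data$region_id)
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(out, "rank")
}

#' Segment one novelty map and extract its ranked proposals
#'
#' Convenience wrapper: threshold, label 8-connected regions, convert to
#' square proposals.
#'
#' @inheritParams extract_proposals
#' @param threshold Cluster threshold `t_k`.
#' @return Proposal tibble (unranked; rank across the whole dataset with
#'   [rank_proposals()]).
#' @export
propose_regions <- function(nm, threshold, min_edge = 30L) {
  mask <- segment_novelty_map(nm, threshold)
  extract_proposals(nm, extract_regions(mask), min_edge = min_edge)
}

#' Export proposals
#'
#' `write_proposals_csv()` writes the proposal table as CSV.
#' `proposals_to_coco()` converts proposals to a COCO-style detection list
#' (`image_id`, `bbox = [x, y, w, h]`, `score`) and optionally writes it
#' as JSON.
#'
#' @param proposals Proposal tibble.
#' @param path Output file.
#' @return `path` invisibly, or the COCO list if `path` is `NULL`.
#' @export
write_proposals_csv <- function(proposals, path) {
  utils::write.csv(proposals, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proposals_csv
#' @export
proposals_to_coco <- function(proposals, path = NULL) {
  dets <- purrr::pmap(proposals, function(image_id, x, y, edge, score,
                                          region_id, ...) {
    list(image_id = image_id, category_id = 1L,
         bbox = c(x, y, edge, edge), score = score)
  })
  if (is.null(path)) return(dets)
  jsonlite::write_json(dets, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write proposal crops as PNG files named by rank
#'
#' @param proposals Ranked proposal tibble (see [rank_proposals()]).
#' @param manifest Manifest covering the proposals' images.
#' @param dir Output directory (created if missing).
#' @param loader Image loader.
#' @return Character vector of written paths, invisibly.
#' @export
write_proposal_crops <- function(proposals, manifest, dir,
                                 loader = load_image) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!"rank" %in% names(proposals)) proposals <- rank_proposals(proposals)
  paths <- character(nrow(proposals))
  for (id in unique(proposals$image_id)) {
    rows <- which(proposals$image_id == id)
    pixels <- loader(manifest$path[manifest$id == id])
    for (i in rows) {
      p <- proposals[i, ]
      crop <- pixels[p$y + seq_len(p$edge), p$x + seq_len(p$edge), ,
                     drop = FALSE]
      paths[i] <- file.path(dir, sprintf("proposal_%05d.png", p$rank))
      save_image_png(crop, paths[i])
    }
  }
  invisible(paths)
}
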