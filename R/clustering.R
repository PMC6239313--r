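#' Shannon entropy of a grayscale histogram
#'
#' Entropy in bits of the histogram of pixel intensities binned into
#' `bins` equal-width bins on `[0, 1]`. A constant image occupies a single
#' bin and has entropy 0; the maximum is `log2(bins)`.
#'
#' @param gray Numeric vector/matrix of intensities in `[0, 1]`.
#' @param bins Number of histogram bins (default 256).
#' @return Scalar entropy in bits.
#' @export
shannon_entropy <- function(gray, bins = 256L) {
  bins <- assert_count(bins, "bins")
  idx <- pmin(floor(as.vector(gray) * bins), bins - 1L)
  p <- tabulate(idx + 1L, nbins = bins)
  p <- p[p > 0] / length(idx)
  -sum(p * log2(p))
}

# grayscale thumbnail of an image, flattened; the raw per-image feature
# the dataset-level PCA is fit on
image_thumbnail <- function(pixels, thumb_size = 32L) {
  assert_pixels(pixels)
  gray <- (pixels[, , 1L] + pixels[, , 2L] + pixels[, , 3L]) / 3
  as.vector(bilinear_resize(gray, thumb_size, thumb_size))
}

#' Per-image appearance features for background clustering
#'
#' Computes the deterministic per-image ingredients of the clustering
#' feature vector: a flattened grayscale thumbnail (default 32 x 32) and
#' the Shannon entropy of the 256-bin grayscale histogram. The thumbnails
#' of a dataset are later projected onto their first principal components
#' and combined with the entropy (see [cluster_images()]).
#'
#' @param pixels `H x W x 3` array in `[0, 1]`.
#' @param thumb_size Thumbnail edge in pixels (default 32).
#' @param bins Histogram bins for the entropy term (default 256).
#' @return List with elements `thumbnail` (numeric vector of length
#'   `thumb_size^2`) and `entropy` (scalar, bits).
#' @export
compute_image_features <- function(pixels, thumb_size = 32L, bins = 256L) {
  assert_pixels(pixels)
  gray <- (pixels[, , 1L] + pixels[, , 2L] + pixels[, , 3L]) / 3
  list(
    thumbnail = image_thumbnail(pixels, thumb_size),
    entropy = shannon_entropy(gray, bins)
  )
}

# squared Euclidean distances, n x k
dist2_to_centers <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) -
    2 * x %*% t(centers)
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, each
# further centre drawn with probability proportional to its squared
# distance to the nearest centre chosen so far
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- dist2_to_centers(x, x[idx[1L], , drop = FALSE])[, 1L]
    for (j in 2:k) {
      d2 <- pmax(d2, 0)
      if (sum(d2) <= 0) {
        idx[j] <- sample.int(n, 1L)
      } else {
        idx[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, dist2_to_centers(x, x[idx[j], , drop = FALSE])[, 1L])
    }
  }
  x[idx, , drop = FALSE]
}

#' Cluster a dataset's images by background appearance
#'
#' Groups the images of a manifest into `K` clusters of globally similar
#' seabed appearance, so that one background model can be trained per
#' cluster. Features are built per dataset: grayscale thumbnails are
#' projected onto their first `n_pcs` principal components, the histogram
#' entropy is appended, and all feature columns are z-scored before
#' k-means. Seeding uses k-means++ with `nstart` independent restarts
#' (best total within-cluster sum of squares wins); a restart that leaves
#' a cluster empty is re-seeded from the point farthest from its assigned
#' centre.
#'
#' @param manifest Manifest tibble.
#' @param K Number of clusters, `1 <= K <=` number of images. The pipeline
#'   default for real surveys is 5.
#' @param seed Integer seed for the restarts.
#' @param n_pcs Number of principal components kept (default 8, capped at
#'   what the data supports).
#' @param thumb_size,bins Feature parameters, see [compute_image_features()].
#' @param nstart Number of k-means++ restarts (default 10).
#' @param loader Image loader, defaults to [load_image()].
#' @return List with `manifest` (input manifest with `cluster_id` filled
#'   in, clusters numbered 1..K) and `model` (a `cluster_model` object
#'   holding centroids and the feature recipe).
#' @export
cluster_images <- function(manifest, K, seed = 1L, n_pcs = 8L,
                           thumb_size = 32L, bins = 256L, nstart = 10L,
                           loader = load_image) {
  K <- assert_count(K, "K")
  if (K > nrow(manifest)) {
    abort(sprintf("K = %d exceeds the number of images (%d).",
                  K, nrow(manifest)))
  }
  feats <- lapply(manifest$path, function(p) {
    compute_image_features(loader(p), thumb_size = thumb_size, bins = bins)
  })
  thumbs <- do.call(rbind, lapply(feats, `[[`, "thumbnail"))
  entropy <- vapply(feats, `[[`, numeric(1), "entropy")

  d <- min(n_pcs, nrow(thumbs) - 1L, ncol(thumbs))
  d <- max(d, 1L)
  pca <- prcomp(thumbs, center = TRUE, scale. = FALSE, rank. = d)
  scores <- pca$x[, seq_len(d), drop = FALSE]
  # PCA scores keep their natural (variance-ordered) scale; the entropy
  # term is centred and rescaled to the median component spread so it
  # contributes without dominating the projection coordinates
  ent_center <- mean(entropy)
  ent_sd <- stats::sd(entropy)
  ent_scale <- if (is.finite(ent_sd) && ent_sd > 0) {
    stats::median(apply(scores, 2L, stats::sd)) / ent_sd
  } else {
    0
  }
  x <- cbind(scores, entropy = (entropy - ent_center) * ent_scale)

  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    fit <- lloyd_kmeans(x, kmeanspp_centers(x, K))
    if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
  }

  model <- structure(
    list(
      K = K, centroids = best$centers, seed = seed,
      sizes = tabulate(best$cluster, K), tot_withinss = best$tot_withinss,
      feature_config = list(thumb_size = thumb_size, bins = bins,
                            n_pcs = d),
      pca_center = pca$center,
      pca_rotation = pca$rotation[, seq_len(d), drop = FALSE],
      entropy_center = ent_center, entropy_scale = ent_scale
    ),
    class = "cluster_model"
  )
  manifest$cluster_id <- as.integer(best$cluster)
  list(manifest = manifest, model = model)
}

# Lloyd iterations with explicit empty-cluster handling: an empty cluster
# is re-seeded from the point farthest from its currently assigned centre.
lloyd_kmeans <- function(x, centers, iter_max = 100L) {
  k <- nrow(centers)
  assign <- NULL
  for (it in seq_len(iter_max)) {
    d2 <- dist2_to_centers(x, centers)
    new_assign <- max.col(-d2, ties.method = "first")
    empty <- which(tabulate(new_assign, k) == 0L)
    for (j in empty) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), new_assign)])
      new_assign[far] <- j
      centers[j, ] <- x[far, ]
      d2 <- dist2_to_centers(x, centers)
    }
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
    }
  }
  d2 <- dist2_to_centers(x, centers)
  list(
    cluster = assign,
    centers = centers,
    tot_withinss = sum(d2[cbind(seq_len(nrow(x)), assign)])
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> K = %d, sizes: %s, tot within-SS = %.3f\n",
              x$K, paste(x$sizes, collapse = "/"), x$tot_withinss))
  invisible(x)
}

#' @export
glance.cluster_model <- function(x, ...) {
  tibble(K = x$K, tot_withinss = x$tot_withinss,
         n_images = sum(x$sizes), seed = x$seed)
}

#' Persist a cluster model as JSON
#'
#' @param model A `cluster_model`.
#' @param path Output JSON path.
#' @return `path` (write) or the restored `cluster_model` (read).
#' @export
write_cluster_model <- function(model, path) {
  obj <- unclass(model)
  for (f in c("centroids", "pca_rotation")) {
    obj[[paste0(f, "_dim")]] <- dim(obj[[f]])
    obj[[f]] <- as.vector(obj[[f]])
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("centroids", "pca_rotation")) {
    obj[[f]] <- matrix(obj[[f]], nrow = obj[[paste0(f, "_dim")]][1])
    obj[[paste0(f, "_dim")]] <- NULL
  }
  structure(obj, class = "cluster_model")
}
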