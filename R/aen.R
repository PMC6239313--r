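#' Configuration of the background-model autoencoder
#'
#' Collects the hyperparameters of the data-driven background model: a
#' single-hidden-layer autoencoder with softplus activations that is
#' trained on randomly sampled background patches and applied
#' convolutionally to score novelty. Defaults follow the published
#' pipeline settings: 39-px patches, compression factor 0.1 (latent size
#' `s = round(0.1 * r)` with `r = 3 * patch_edge^2`), Adam with learning
#' rate 1e-3, 100 epochs, minibatch 128, 10^4 training patches.
#'
#' @param patch_edge Odd patch edge length in pixels (>= 3; 29 and 39 are
#'   the grid values of the published parameter search).
#' @param compression Latent compression factor `s_c` in (0, 1).
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param minibatch Minibatch size.
#' @param n_train_patches Number of random training patches per cluster.
#' @param seed Integer seed controlling patch sampling, weight
#'   initialisation and epoch shuffling.
#' @param slice_rows Number of patch-grid rows processed per slice when the
#'   model is applied convolutionally (memory knob; the result is
#'   independent of it).
#' @return An `aen_config` list with derived fields `input_dim`
#'   (`r = 3 * patch_edge^2`) and `latent_dim` (`s = round(compression * r)`).
#' @examples
#' aen_config()$latent_dim  # 456 for the 39-px default
#' @export
aen_config <- function(patch_edge = 39L, compression = 0.1,
                       learning_rate = 1e-3, epochs = 100L,
                       minibatch = 128L, n_train_patches = 10000L,
                       seed = 1L, slice_rows = 8L) {
  patch_edge <- assert_odd_edge(patch_edge, "patch_edge", min = 3L)
  assert_scalar_number(compression, "compression")
  if (compression <= 0 || compression >= 1) {
    abort("`compression` must lie strictly between 0 and 1.")
  }
  assert_scalar_number(learning_rate, "learning_rate", min = 0)
  r <- 3L * patch_edge^2
  s <- as.integer(round(compression * r))
  if (s < 1L || s >= r) {
    abort("Derived latent size must satisfy 1 <= s < r.")
  }
  structure(
    list(
      patch_edge = patch_edge, compression = compression,
      learning_rate = learning_rate,
      epochs = assert_count(epochs, "epochs"),
      minibatch = assert_count(minibatch, "minibatch"),
      n_train_patches = assert_count(n_train_patches, "n_train_patches"),
      seed = assert_count(seed, "seed", min = 0L),
      slice_rows = assert_count(slice_rows, "slice_rows"),
      input_dim = r, latent_dim = s
    ),
    class = "aen_config"
  )
}

#' @export
print.aen_config <- function(x, ...) {
  cat(sprintf(
    "<aen_config> patch %dpx (r = %d), latent %d (s_c = %g), %d epochs x batch %d, lr %g\n",
    x$patch_edge, x$input_dim, x$latent_dim, x$compression, x$epochs,
    x$minibatch, x$learning_rate))
  invisible(x)
}

new_dbm <- function(W, b, W_dec, b_dec, config, cluster_id = NA_integer_,
                    epoch_loss = NULL) {
  stopifnot(
    nrow(W) == config$latent_dim, ncol(W) == config$input_dim,
    length(b) == config$latent_dim,
    nrow(W_dec) == config$input_dim, ncol(W_dec) == config$latent_dim,
    length(b_dec) == config$input_dim
  )
  if (!all(is.finite(W)) || !all(is.finite(W_dec)) ||
      !all(is.finite(b)) || !all(is.finite(b_dec))) {
    abort("Background-model weights must all be finite.")
  }
  structure(
    list(W = W, b = as.numeric(b), W_dec = W_dec, b_dec = as.numeric(b_dec),
         config = config, cluster_id = as.integer(cluster_id),
         epoch_loss = epoch_loss),
    class = "dbm"
  )
}

#' @export
print.dbm <- function(x, ...) {
  cat(sprintf("<dbm> cluster %s: r = %d -> s = %d", x$cluster_id,
              x$config$input_dim, x$config$latent_dim))
  if (!is.null(x$epoch_loss)) {
    cat(sprintf(", training error %.4g -> %.4g over %d epochs",
                x$epoch_loss[1], tail(x$epoch_loss, 1),
                length(x$epoch_loss)))
  }
  cat("\n")
  invisible(x)
}

#' Encode / decode patches with a background model
#'
#' `encode()` maps flattened patches to the latent representation
#' `l = softplus(W x + b)`; `decode()` reconstructs
#' `x' = softplus(W' l + b')`. Both accept a single vector or an
#' `r x n` / `s x n` column matrix.
#'
#' @param x Patch vector of length `r` or matrix `r x n`.
#' @param dbm A trained background model (see [train_dbm()]).
#' @return Latent vector/matrix (`encode`) or reconstruction (`decode`).
#' @export
encode <- function(x, dbm) {
  x <- as_cols(x, dbm$config$input_dim, "x")
  softplus(dbm$W %*% x + dbm$b)
}

#' @rdname encode
#' @param l Latent vector of length `s` or matrix `s x n`.
#' @export
decode <- function(l, dbm) {
  l <- as_cols(l, dbm$config$latent_dim, "l")
  softplus(dbm$W_dec %*% l + dbm$b_dec)
}

as_cols <- function(x, d, name) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (nrow(x) != d) {
    abort(sprintf("`%s` must have %d components per column, got %d.",
                  name, d, nrow(x)))
  }
  x
}

#' Reconstruction error of a patch
#'
#' The novelty score of a single patch: the sum of squared componentwise
#' differences between a patch and its reconstruction,
#' `F(x, x') = sum((x - x')^2)`.
#'
#' @param x,xprime Equal-length vectors, or equal-dimension column
#'   matrices (error computed per column).
#' @return Nonnegative scalar (or vector, one per column).
#' @export
reconstruction_error <- function(x, xprime) {
  if (is.null(dim(x)) != is.null(dim(xprime)) ||
      !identical(dim(x), dim(xprime)) || length(x) != length(xprime)) {
    abort("`x` and `xprime` must have identical dimensions.")
  }
  if (is.null(dim(x))) {
    sum((x - xprime)^2)
  } else {
    colSums((x - xprime)^2)
  }
}

#' Train a data-driven background model for one image cluster
#'
#' Samples `n_train_patches` random patches from the cluster's images and
#' trains the autoencoder to reconstruct them, minimising the minibatch
#' mean of the summed squared reconstruction error with Adam (fixed
#' learning rate) for `epochs` epochs. Weights are Xavier-initialised
#' (uniform Glorot, both layers); biases start at zero. All randomness
#' derives from `config$seed`, so training is reproducible.
#'
#' @param manifest Manifest tibble of the cluster's images (pass a
#'   pre-filtered manifest, or use `cluster_id` to filter).
#' @param config An [aen_config()].
#' @param cluster_id Optional cluster id; when given, `manifest` is
#'   filtered to rows with that `cluster_id` and the id is stored on the
#'   model.
#' @param loader Image loader.
#' @return A `dbm` object with weights, the config and the per-epoch mean
#'   training error (`epoch_loss`).
#' @export
train_dbm <- function(manifest, config = aen_config(),
                      cluster_id = NA_integer_, loader = load_image) {
  if (!is.na(cluster_id)) {
    manifest <- manifest[!is.na(manifest$cluster_id) &
                           manifest$cluster_id == cluster_id, , drop = FALSE]
  }
  if (nrow(manifest) == 0L) {
    abort("Cannot train a background model on an empty image cluster.")
  }
  set.seed(config$seed)
  centers <- sample_patch_centers(manifest, config$n_train_patches,
                                  config$patch_edge)
  X <- extract_patch_matrix(manifest, centers, loader = loader)
  r <- config$input_dim
  s <- config$latent_dim
  lim <- sqrt(6 / (r + s))                      # Glorot uniform bound
  W <- matrix(runif(s * r, -lim, lim), s, r)
  W_dec <- matrix(runif(r * s, -lim, lim), r, s)
  n <- config$n_train_patches
  order_mat <- vapply(seq_len(config$epochs),
                      function(e) sample.int(n) - 1L, integer(n))
  fit <- cpp_train_aen(X, W, rep(0, s), W_dec, rep(0, r),
                       config$epochs, config$minibatch,
                       config$learning_rate, order_mat)
  new_dbm(fit$W, fit$b, fit$W_dec, fit$b_dec, config,
          cluster_id = cluster_id, epoch_loss = as.numeric(fit$epoch_loss))
}

#' @export
tidy.dbm <- function(x, ...) {
  tibble(epoch = seq_along(x$epoch_loss %||% numeric()),
         mean_error = as.numeric(x$epoch_loss %||% numeric()))
}

#' @export
glance.dbm <- function(x, ...) {
  el <- x$epoch_loss %||% NA_real_
  tibble(
    cluster_id = x$cluster_id,
    patch_edge = x$config$patch_edge,
    input_dim = x$config$input_dim,
    latent_dim = x$config$latent_dim,
    epochs = x$config$epochs,
    initial_error = el[1],
    final_error = tail(el, 1)
  )
}

#' @export
autoplot.dbm <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$mean_error)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean training error",
                  title = "Background-model training curve") +
    ggplot2::theme_minimal()
}

#' Compute the novelty map of an image
#'
#' Applies a trained background model convolutionally: every patch whose
#' support fits inside the image (stepping `stride` pixels in x and y) is
#' encoded, decoded, and its reconstruction error stored at the patch
#' centre. The stride-reduced error grid is then upscaled to the full
#' image resolution by bilinear interpolation, with edge replication into
#' the margin not covered by any patch centre, so the returned map has the
#' same height and width as the image. Processing happens in horizontal
#' slices of the patch grid; the result is independent of the slicing.
#'
#' @param pixels `H x W x 3` array in `[0, 1]`.
#' @param dbm Trained background model.
#' @param stride Convolution stride in pixels (default 2).
#' @param image_id Identifier stored on the map (defaults to the array's
#'   `"path"` attribute, if any).
#' @return A `novelty_map` object: list with `values` (`H x W` matrix of
#'   nonnegative scores), `image_id`, `dilated` flag, and the `patch_edge`
#'   and `stride` used.
#' @export
apply_dbm <- function(pixels, dbm, stride = 2L, image_id = NULL) {
  assert_pixels(pixels)
  stride <- assert_count(stride, "stride", min = 1L)
  edge <- dbm$config$patch_edge
  H <- dim(pixels)[1]
  W <- dim(pixels)[2]
  if (H < edge || W < edge) {
    abort(sprintf("Image (%d x %d) is smaller than the patch edge %d.",
                  W, H, edge))
  }
  grid <- cpp_apply_aen(pixels[, , 1L], pixels[, , 2L], pixels[, , 3L],
                        dbm$W, dbm$b, dbm$W_dec, dbm$b_dec,
                        edge, stride, dbm$config$slice_rows)
  values <- upscale_novelty_grid(grid, H, W, edge, stride)
  new_novelty_map(values, image_id %||% attr(pixels, "path") %||% NA_character_,
                  dilated = FALSE, patch_edge = edge, stride = stride)
}

# map the stride-reduced grid (rows index y) back to H x W: grid node (i, j)
# sits at pixel centre (h + stride*i, h + stride*j); pixels outside the
# centre lattice replicate the nearest interpolated value
upscale_novelty_grid <- function(grid, H, W, edge, stride) {
  h <- (edge - 1L) %/% 2L
  wy <- interp_weights((seq_len(H) - 1 - h) / stride, nrow(grid))
  wx <- interp_weights((seq_len(W) - 1 - h) / stride, ncol(grid))
  wy %*% grid %*% t(wx)
}

new_novelty_map <- function(values, image_id, dilated, patch_edge, stride) {
  structure(
    list(values = values, image_id = image_id, dilated = dilated,
         patch_edge = patch_edge, stride = stride),
    class = "novelty_map"
  )
}

#' @export
print.novelty_map <- function(x, ...) {
  cat(sprintf("<novelty_map> %s: %d x %d, %s, max %.4g\n",
              x$image_id, ncol(x$values), nrow(x$values),
              if (x$dilated) "dilated" else "raw", max(x$values)))
  invisible(x)
}

#' Dilate a novelty map
#'
#' Convolves the map with an all-ones square kernel (zero padding outside
#' the image, shape preserved). The kernel defaults to the training-patch
#' edge, which smooths and thickens high-novelty regions before
#' thresholding so that nearby responses merge into one region.
#'
#' @param nm A `novelty_map`.
#' @param kernel_edge Odd kernel edge in pixels; defaults to the map's
#'   `patch_edge`.
#' @return The dilated `novelty_map` (`dilated = TRUE`).
#' @export
dilate_novelty_map <- function(nm, kernel_edge = NULL) {
  kernel_edge <- assert_odd_edge(kernel_edge %||% nm$patch_edge,
                                 "kernel_edge")
  nm$values <- box_sum(nm$values, kernel_edge)
  nm$dilated <- TRUE
  nm
}

#' @export
autoplot.novelty_map <- function(object, ...) {
  df <- tidyr::expand_grid(y = seq_len(nrow(object$values)) - 1L,
                           x = seq_len(ncol(object$values)) - 1L)
  df$novelty <- as.vector(t(object$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$novelty)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$image_id) +
    ggplot2::theme_minimal()
}

#' Serialise a background model
#'
#' Writes weights, biases and the configuration to a single JSON file (and
#' reads it back).
#'
#' @param dbm A `dbm`.
#' @param path File path.
#' @return `path` (write) / the restored `dbm` (read).
#' @export
write_dbm <- function(dbm, path) {
  obj <- list(
    cluster_id = dbm$cluster_id,
    config = unclass(dbm$config),
    epoch_loss = dbm$epoch_loss,
    W = as.vector(dbm$W), b = dbm$b,
    W_dec = as.vector(dbm$W_dec), b_dec = dbm$b_dec
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_dbm
#' @export
read_dbm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$cluster_id)) obj$cluster_id <- NA_integer_
  config <- do.call(aen_config, obj$config[c(
    "patch_edge", "compression", "learning_rate", "epochs", "minibatch",
    "n_train_patches", "seed", "slice_rows")])
  new_dbm(matrix(obj$W, config$latent_dim, config$input_dim), obj$b,
          matrix(obj$W_dec, config$input_dim, config$latent_dim), obj$b_dec,
          config, cluster_id = obj$cluster_id, epoch_loss = obj$epoch_loss)
}

#' Export / import a novelty map as 32-bit float TIFF
#'
#' Novelty scores are unbounded above, while the TIFF writer stores
#' normalised floats, so the map is written as `values / scale` with the
#' scale (the map's maximum) and the map metadata in a JSON sidecar file
#' (`<path>.json`); `read_novelty_map()` restores the original values.
#'
#' @param nm A `novelty_map`.
#' @param path `.tif` path.
#' @return `path` invisibly (write) / the restored `novelty_map` (read).
#' @export
write_novelty_map <- function(nm, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("Novelty-map TIFF export requires the 'tiff' package.")
  }
  scale <- max(nm$values, .Machine$double.xmin)
  tiff::writeTIFF(nm$values / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  jsonlite::write_json(
    list(scale = scale, image_id = nm$image_id, dilated = nm$dilated,
         patch_edge = nm$patch_edge, stride = nm$stride),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_novelty_map
#' @export
read_novelty_map <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("Novelty-map TIFF import requires the 'tiff' package.")
  }
  img <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_novelty_map(img * meta$scale, meta$image_id %||% NA_character_,
                  meta$dilated, meta$patch_edge, meta$stride)
}
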