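#' Load an RGB seabed image
#'
#' Reads a PNG, TIFF or JPEG image and returns its pixels as an
#' `H x W x 3` numeric array with values rescaled to `[0, 1]` (8- and
#' 16-bit inputs are divided by their dtype maximum by the format readers).
#' Grayscale images are promoted to three identical channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to an image file (`.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg`).
#' @return Numeric `H x W x 3` array in `[0, 1]` with attribute `"path"`.
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    abort("`path` must be a single file path.")
  }
  if (!file.exists(path)) {
    abort(sprintf("Cannot read image: file does not exist: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  pixels <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = {
        if (!requireNamespace("tiff", quietly = TRUE)) {
          abort("Reading TIFF images requires the 'tiff' package.")
        }
        tiff::readTIFF(path)
      },
      jpg = ,
      jpeg = {
        if (!requireNamespace("jpeg", quietly = TRUE)) {
          abort("Reading JPEG images requires the 'jpeg' package.")
        }
        jpeg::readJPEG(path)
      },
      abort(sprintf("Unsupported image format '%s' for %s", ext, path))
    ),
    error = function(e) {
      abort(sprintf("Cannot decode image %s: %s", path, conditionMessage(e)))
    }
  )
  if (length(pixels) == 0L) {
    abort(sprintf("Zero-sized image: %s", path))
  }
  if (is.matrix(pixels)) {                       # grayscale -> 3 channels
    pixels <- array(pixels, dim = c(dim(pixels), 3L))
  }
  if (dim(pixels)[3] > 3L) {                     # drop alpha
    pixels <- pixels[, , 1:3, drop = FALSE]
  }
  if (dim(pixels)[3] == 1L) {
    pixels <- array(pixels[, , 1L], dim = c(dim(pixels)[1:2], 3L))
  }
  pixels <- pmin(pmax(pixels, 0), 1)
  dn <- dim(pixels)
  if (any(dn[1:2] < 1L)) {
    abort(sprintf("Zero-sized image: %s", path))
  }
  structure(pixels, path = path)
}

#' Write an RGB image to a PNG file
#'
#' @param pixels `H x W x 3` array in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_image_png <- function(pixels, path) {
  assert_pixels(pixels)
  png::writePNG(pmin(pmax(pixels, 0), 1), target = path)
  invisible(path)
}

#' Build a dataset manifest
#'
#' A manifest is the tabular record of an image dataset: one row per image
#' with its identifier, file path, pixel dimensions and (once clustering has
#' run) background-cluster assignment.
#'
#' @param paths Character vector of image file paths.
#' @param ids Optional identifiers; defaults to the file names without
#'   extension. Must be unique.
#' @return A tibble with columns `id`, `path`, `width`, `height`,
#'   `cluster_id`.
#' @export
image_manifest <- function(paths, ids = NULL) {
  ids <- ids %||% tools::file_path_sans_ext(basename(paths))
  if (anyDuplicated(ids)) {
    abort("Image ids must be unique within a dataset.")
  }
  dims <- vapply(paths, function(p) dim(load_image(p))[1:2], integer(2))
  tibble(
    id = as.character(ids),
    path = as.character(paths),
    width = as.integer(dims[2L, ]),
    height = as.integer(dims[1L, ]),
    cluster_id = NA_integer_
  )
}

#' Read / write a dataset manifest CSV
#'
#' @param path CSV file with columns `id,path,width,height,cluster_id`.
#' @return `read_manifest()` returns the manifest tibble; `write_manifest()`
#'   returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "path", "width", "height", "cluster_id")
  if (!all(need %in% names(df))) {
    abort(sprintf("Manifest %s must have columns %s.", path,
                  paste(need, collapse = ", ")))
  }
  df$id <- as.character(df$id)
  df$cluster_id <- as.integer(df$cluster_id)
  as_tibble(df)
}

#' @rdname read_manifest
#' @param manifest Manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Enumerate the patch-centre grid of an image
#'
#' Lists the centres of all square `edge x edge` patches that fit fully
#' inside a `width x height` image, stepping by `stride` pixels in x and y.
#' Coordinates are 0-based (x right, y down) and enumeration is row-major:
#' y varies slowest, x fastest. This is the grid the background model is
#' applied on when it is run convolutionally.
#'
#' @param width,height Image dimensions in pixels.
#' @param edge Odd patch edge length in pixels.
#' @param stride Step in pixels (default 2, the convolution stride used for
#'   novelty-map computation).
#' @return Tibble with columns `cx`, `cy` (0-based patch centres).
#' @export
patch_grid <- function(width, height, edge, stride = 2L) {
  edge <- assert_odd_edge(edge, "edge")
  stride <- assert_count(stride, "stride", min = 1L)
  width <- assert_count(width, "width")
  height <- assert_count(height, "height")
  if (width < edge || height < edge) {
    abort(sprintf("Image (%d x %d) is smaller than the patch edge %d.",
                  width, height, edge))
  }
  h <- (edge - 1L) %/% 2L
  xs <- seq.int(0L, width - edge, by = stride) + h
  ys <- seq.int(0L, height - edge, by = stride) + h
  tibble(
    cx = rep(xs, times = length(ys)),
    cy = rep(ys, each = length(xs))
  )
}

#' Sample random training patches from a set of images
#'
#' Draws `n` square patches with replacement: for each patch an image is
#' chosen uniformly from the manifest, then a valid centre position is
#' chosen uniformly over all positions where the patch fits fully inside
#' that image. This is the sampling used to collect the training set of a
#' data-driven background model (10^4 patches by default in the pipeline).
#'
#' @param manifest Manifest tibble (typically one background cluster).
#' @param n Number of patches.
#' @param edge Odd patch edge in pixels.
#' @param seed Optional integer; when given, the draw is made reproducible
#'   with `set.seed()`.
#' @return Tibble with columns `image_id`, `cx`, `cy`, `edge` (0-based
#'   centres), one row per patch.
#' @export
sample_patch_centers <- function(manifest, n, edge, seed = NULL) {
  n <- assert_count(n, "n")
  edge <- assert_odd_edge(edge, "edge")
  too_small <- manifest$width < edge | manifest$height < edge
  if (any(too_small)) {
    abort(sprintf("Images smaller than patch edge %d: %s", edge,
                  paste(manifest$id[too_small], collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  h <- (edge - 1L) %/% 2L
  pick <- sample.int(nrow(manifest), n, replace = TRUE)
  nx <- manifest$width[pick] - edge + 1L
  ny <- manifest$height[pick] - edge + 1L
  tibble(
    image_id = manifest$id[pick],
    cx = as.integer(floor(runif(n) * nx)) + h,
    cy = as.integer(floor(runif(n) * ny)) + h,
    edge = edge
  )
}

#' Extract flattened patch vectors
#'
#' Crops the patches listed in `centers` and flattens each to a column of
#' length `r = 3 * edge^2`: pixels in row-major order within the patch,
#' RGB interleaved per pixel.
#'
#' @param manifest Manifest tibble covering every `image_id` in `centers`.
#' @param centers Tibble as returned by [sample_patch_centers()] or
#'   [patch_grid()] (the latter needs an `image_id` column added).
#' @param loader Function mapping a path to a pixel array; defaults to
#'   [load_image()].
#' @return Numeric matrix `r x nrow(centers)`, columns in `centers` order.
#' @export
extract_patch_matrix <- function(manifest, centers, loader = load_image) {
  if (!all(centers$image_id %in% manifest$id)) {
    abort("`centers` references image ids missing from the manifest.")
  }
  edge <- unique(centers$edge)
  if (length(edge) != 1L) {
    abort("All patches must share one edge length.")
  }
  edge <- assert_odd_edge(edge, "edge")
  r <- 3L * edge * edge
  out <- matrix(NA_real_, r, nrow(centers))
  for (id in unique(centers$image_id)) {
    rows <- which(centers$image_id == id)
    pixels <- loader(manifest$path[manifest$id == id])
    out[, rows] <- extract_patches(pixels, centers$cx[rows],
                                   centers$cy[rows], edge)
  }
  out
}

#' @rdname extract_patch_matrix
#' @param pixels `H x W x 3` array.
#' @param cx,cy Integer vectors of 0-based patch centres.
#' @param edge Odd patch edge.
#' @export
extract_patches <- function(pixels, cx, cy, edge) {
  assert_pixels(pixels)
  edge <- assert_odd_edge(edge, "edge")
  h <- (edge - 1L) %/% 2L
  H <- dim(pixels)[1]
  W <- dim(pixels)[2]
  if (any(cx < h | cx > W - 1L - h | cy < h | cy > H - 1L - h)) {
    abort("Patch centres place patches outside the image.")
  }
  cpp_extract_patches(pixels[, , 1L], pixels[, , 2L], pixels[, , 3L],
                      as.integer(cx), as.integer(cy), edge)
}
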