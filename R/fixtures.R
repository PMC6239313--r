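# Synthetic seabed imagery with known ground truth: textured sediment
# backgrounds with rare planted objects, so every pipeline stage can be
# exercised (and its recall measured) without any survey data.

sediment_presets <- list(
  smooth_sand = list(base = c(0.76, 0.70, 0.55), noise_sd = 0.04,
                     grain = 9L),
  gravel      = list(base = c(0.45, 0.42, 0.38), noise_sd = 0.12,
                     grain = 3L),
  dark_mud    = list(base = c(0.22, 0.18, 0.14), noise_sd = 0.05,
                     grain = 5L)
)

object_palette <- list(
  animal = c(0.95, 0.93, 0.85),
  shell  = c(0.92, 0.88, 0.95)
)

#' Specification of a synthetic seabed image
#'
#' Describes one generated image: a textured sediment background (base
#' colour plus band-limited noise, per sediment type), an optional smooth
#' illumination gradient, and rare planted objects with known class,
#' position and size. Object pixels are kept rare by construction — the
#' novelty-detection assumption the generator exists to emulate — and
#' generation warns if they exceed `rarity_bound`.
#'
#' @param width,height Image size in pixels.
#' @param sediment_type One of `"smooth_sand"`, `"gravel"`, `"dark_mud"`.
#' @param illumination Strength of a smooth radial illumination falloff in
#'   `[0, 1]` (0 = flat lighting).
#' @param density Expected number of planted objects per image.
#' @param object_templates Tibble with columns `shape` (`disk`, `ellipse`,
#'   `blob`), `size` (radius-like scale, px), `contrast` (`[0, 1]` mix
#'   towards the object colour) and `class`.
#' @param rarity_bound Warn if planted-object pixels exceed this fraction
#'   of the image (default 0.02).
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(width = 512L, height = 512L,
                         sediment_type = "smooth_sand", illumination = 0,
                         density = 2L,
                         object_templates = default_object_templates(),
                         rarity_bound = 0.02, seed = 1L) {
  if (!sediment_type %in% names(sediment_presets)) {
    abort(sprintf("Unknown sediment type '%s'; available: %s",
                  sediment_type,
                  paste(names(sediment_presets), collapse = ", ")))
  }
  if (density < 0) abort("`density` must be nonnegative.")
  structure(
    list(width = assert_count(width, "width"),
         height = assert_count(height, "height"),
         sediment_type = sediment_type,
         illumination = illumination,
         density = as.integer(density),
         object_templates = object_templates,
         rarity_bound = rarity_bound,
         seed = assert_count(seed, "seed", min = 0L)),
    class = "fixture_spec"
  )
}

#' @rdname fixture_spec
#' @export
default_object_templates <- function() {
  tibble(
    shape = c("disk", "ellipse", "blob"),
    size = c(12, 15, 11),
    contrast = c(0.95, 0.85, 0.9),
    class = c("animal", "shell", "animal")
  )
}

# band-limited noise: blurred white noise, renormalised to unit sd
textured_noise <- function(H, W, grain) {
  m <- matrix(rnorm(H * W), H, W)
  if (grain > 1L) {
    k <- as.integer(grain)
    if (k %% 2L == 0L) k <- k + 1L
    m <- box_sum(m - min(m), k) / k^2      # box blur of shifted noise
    m <- m - mean(m)
  }
  m / stats::sd(m)
}

render_object <- function(canvas, shape, cx, cy, size, colour, contrast,
                          angle) {
  H <- dim(canvas)[1]
  W <- dim(canvas)[2]
  xs <- matrix(rep(0:(W - 1), each = H), H, W) - cx
  ys <- matrix(rep(0:(H - 1), W), H, W) - cy
  u <- cos(angle) * xs + sin(angle) * ys
  v <- -sin(angle) * xs + cos(angle) * ys
  inside <- switch(shape,
    disk = xs^2 + ys^2 <= size^2,
    ellipse = (u / size)^2 + (v / (0.6 * size))^2 <= 1,
    blob = {
      off <- 0.45 * size
      sub <- 0.65 * size
      (u - off)^2 + v^2 <= sub^2 | (u + off)^2 + v^2 <= sub^2 |
        u^2 + (v - off)^2 <= sub^2
    },
    abort(sprintf("Unknown object shape '%s'.", shape))
  )
  for (ch in 1:3) {
    layer <- canvas[, , ch]
    layer[inside] <- (1 - contrast) * layer[inside] + contrast * colour[ch]
    canvas[, , ch] <- layer
  }
  # tight enclosing circle of the rendered support
  radius <- switch(shape, disk = size, ellipse = size,
                   blob = 0.45 * size + 0.65 * size)
  list(canvas = canvas, radius = radius, n_pixels = sum(inside))
}

#' Generate one synthetic seabed image
#'
#' Renders the background texture, applies the illumination gradient and
#' plants `density` objects at random non-overlapping positions.
#'
#' @param spec A [fixture_spec()].
#' @param image_id Identifier recorded in the ground truth.
#' @return List with `pixels` (`H x W x 3` in `[0, 1]`) and `truth`
#'   (circle tibble: `image_id`, `cx`, `cy`, `radius`, `label`,
#'   `provenance = "truth"`).
#' @export
generate_image <- function(spec, image_id = "fixture") {
  set.seed(spec$seed)
  generate_image_impl(spec, image_id)
}

# RNG-stream version used by generate_dataset (no reseeding)
generate_image_impl <- function(spec, image_id) {
  preset <- sediment_presets[[spec$sediment_type]]
  H <- spec$height
  W <- spec$width
  noise <- textured_noise(H, W, preset$grain) * preset$noise_sd
  pixels <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) {
    pixels[, , ch] <- preset$base[ch] + noise +
      0.3 * preset$noise_sd * rnorm(H * W)
  }
  if (spec$illumination > 0) {
    xs <- matrix(rep(0:(W - 1), each = H), H, W) / (W - 1) - 0.5
    ys <- matrix(rep(0:(H - 1), W), H, W) / (H - 1) - 0.5
    falloff <- 1 - spec$illumination * 2 * (xs^2 + ys^2)
    for (ch in 1:3) pixels[, , ch] <- pixels[, , ch] * falloff
  }
  truth <- tibble(image_id = character(), cx = numeric(), cy = numeric(),
                  radius = numeric(), label = character(),
                  provenance = character())
  placed <- matrix(numeric(0), 0, 3)  # cx, cy, radius
  object_pixels <- 0
  n_obj <- spec$density
  for (k in seq_len(n_obj)) {
    tpl <- spec$object_templates[
      sample.int(nrow(spec$object_templates), 1L), ]
    margin <- ceiling(2 * tpl$size) + 1
    if (W - 2 * margin <= 0 || H - 2 * margin <= 0) {
      abort("Objects do not fit inside the image.")
    }
    ok <- FALSE
    for (try in 1:100) {
      cx <- margin + floor(runif(1) * (W - 2 * margin))
      cy <- margin + floor(runif(1) * (H - 2 * margin))
      if (nrow(placed) == 0 ||
          all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                2 * (placed[, 3] + 2 * tpl$size))) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort("Could not place a non-overlapping object after 100 tries.")
    }
    angle <- runif(1, 0, pi)
    rend <- render_object(pixels, tpl$shape, cx, cy, tpl$size,
                          object_palette[[tpl$class]] %||% c(0.95, 0.95, 0.9),
                          tpl$contrast, angle)
    pixels <- rend$canvas
    object_pixels <- object_pixels + rend$n_pixels
    placed <- rbind(placed, c(cx, cy, rend$radius))
    truth <- dplyr::bind_rows(truth, tibble(
      image_id = image_id, cx = cx, cy = cy, radius = rend$radius,
      label = tpl$class, provenance = "truth"))
  }
  if (object_pixels / (H * W) > spec$rarity_bound) {
    warn(sprintf(
      "Planted objects cover %.2f%% of the image, above the rarity bound of %.2f%%; novelty detection assumes rare objects.",
      100 * object_pixels / (H * W), 100 * spec$rarity_bound))
  }
  list(pixels = pmin(pmax(pixels, 0), 1), truth = truth)
}

#' Generate a synthetic seabed dataset on disk
#'
#' Writes `n_images` PNG images drawn from a mix of sediment types, plus
#' the dataset manifest and ground-truth circle CSVs. Sediment labels are
#' recorded in the manifest (`sediment` column) for validating background
#' clustering.
#'
#' @param dir Output directory (created if needed).
#' @param n_images Number of images.
#' @param type_mix Named proportions over sediment types (must sum to 1),
#'   e.g. `c(smooth_sand = 0.5, dark_mud = 0.5)`. Counts are rounded,
#'   remainders going to the first types.
#' @param template A [fixture_spec()] supplying everything but the
#'   sediment type.
#' @param seed Integer seed for the whole dataset.
#' @return List with `manifest` (including `sediment`), `truth`, and the
#'   paths of the written `manifest.csv` / `ground_truth.csv`.
#' @export
generate_dataset <- function(dir, n_images = 20L,
                             type_mix = c(smooth_sand = 0.5, dark_mud = 0.5),
                             template = fixture_spec(), seed = 1L) {
  n_images <- assert_count(n_images, "n_images")
  if (abs(sum(type_mix) - 1) > 1e-8) {
    abort("`type_mix` proportions must sum to 1.")
  }
  if (!all(names(type_mix) %in% names(sediment_presets))) {
    abort("`type_mix` names must be known sediment types.")
  }
  counts <- floor(type_mix * n_images)
  rem <- n_images - sum(counts)
  if (rem > 0) {
    counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  }
  types <- rep(names(counts), counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  rows <- vector("list", n_images)
  truths <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    id <- sprintf("img_%03d", i)
    spec_i <- template
    spec_i$sediment_type <- types[i]
    out <- generate_image_impl(spec_i, image_id = id)
    path <- file.path(dir, paste0(id, ".png"))
    save_image_png(out$pixels, path)
    rows[[i]] <- tibble(id = id, path = path,
                        width = spec_i$width, height = spec_i$height,
                        cluster_id = NA_integer_, sediment = types[i])
    truths[[i]] <- out$truth
  }
  manifest <- dplyr::bind_rows(rows)
  truth <- dplyr::bind_rows(truths)
  manifest_path <- file.path(dir, "manifest.csv")
  truth_path <- file.path(dir, "ground_truth.csv")
  write_manifest(manifest, manifest_path)
  write_circles(truth, truth_path)
  list(manifest = manifest, truth = truth,
       manifest_path = manifest_path, truth_path = truth_path)
}
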