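#' Apply manual filtering decisions to ranked proposals
#'
#' Models the grid-review step: a human works through the ranked proposal
#' list from the top and either rejects a proposal or assigns it a class
#' label. Decisions must cover a prefix of the ranking (review stops at
#' some point). Accepted proposals beyond the per-class limit (600 by
#' default) are dropped, per class, in rank order.
#'
#' @param ranked Ranked proposal tibble (see [rank_proposals()]).
#' @param decisions Tibble with columns `image_id`, `region_id`, `label`
#'   (`NA` label = rejected). Each row must match a proposal and the
#'   decided proposals must form a prefix of the ranking.
#' @param per_class_limit Maximum retained proposals per class.
#' @return Tibble of accepted proposals with a `label` column, in rank
#'   order, with attribute `"class_counts"` (tibble of accepted counts per
#'   class).
#' @export
filter_proposals <- function(ranked, decisions, per_class_limit = 600L) {
  per_class_limit <- assert_count(per_class_limit, "per_class_limit")
  key <- function(df) paste(df$image_id, df$region_id, sep = "\r")
  miss <- !(key(decisions) %in% key(ranked))
  if (any(miss)) {
    abort(sprintf("Decisions reference unknown proposals: %s",
                  paste(decisions$image_id[miss], decisions$region_id[miss],
                        sep = "/", collapse = ", ")))
  }
  pos <- match(key(decisions), key(ranked))
  if (length(pos) > 0 && !setequal(pos, seq_len(max(pos)))) {
    abort("Decisions must cover a prefix of the ranked proposal list.")
  }
  decided <- ranked[sort(pos), , drop = FALSE]
  decided$label <- decisions$label[match(key(decided), key(decisions))]
  accepted <- decided[!is.na(decided$label), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(accepted)), accepted$label),
                        head, per_class_limit), use.names = FALSE)
  accepted <- accepted[sort(keep), , drop = FALSE]
  counts <- dplyr::count(accepted, .data$label, name = "n_accepted")
  attr(accepted, "class_counts") <- counts
  accepted
}

#' Simulate review decisions from ground truth
#'
#' Stand-in for the human filtering step in end-to-end runs: a proposal is
#' "accepted" with the class of a ground-truth object whose centre lies in
#' its box, and rejected otherwise.
#'
#' @param ranked Ranked proposal tibble.
#' @param truth Ground-truth circle tibble (`image_id`, `cx`, `cy`,
#'   `label`).
#' @return Decision tibble usable with [filter_proposals()].
#' @export
decide_proposals_from_truth <- function(ranked, truth) {
  lab <- vapply(seq_len(nrow(ranked)), function(i) {
    p <- ranked[i, ]
    hit <- truth$image_id == p$image_id &
      truth$cx >= p$x & truth$cx <= p$x + p$edge - 1L &
      truth$cy >= p$y & truth$cy <= p$y + p$edge - 1L
    if (any(hit)) truth$label[which(hit)[1L]] else NA_character_
  }, character(1))
  tibble(image_id = ranked$image_id, region_id = ranked$region_id,
         label = lab)
}

#' Default circle suggestion for accepted proposals
#'
#' The refinement step starts from the inscribed circle of each proposal
#' box: centre at the box centre, radius half the edge.
#'
#' @param proposals Proposal tibble (with `label` if already filtered).
#' @return Circle tibble (`image_id`, `cx`, `cy`, `radius`, `label`,
#'   `provenance = "proposal"`).
#' @export
proposal_circles <- function(proposals) {
  tibble(
    image_id = proposals$image_id,
    cx = proposals$x + (proposals$edge - 1) / 2,
    cy = proposals$y + (proposals$edge - 1) / 2,
    radius = proposals$edge / 2,
    label = if ("label" %in% names(proposals)) proposals$label else
      rep(NA_character_, nrow(proposals)),
    provenance = "proposal"
  )
}

#' Record the human refinement of one training proposal
#'
#' Stores the reviewer-adjusted circle for a proposal. Unadjusted fields
#' default to the proposal's inscribed circle.
#'
#' @param proposal One proposal row.
#' @param cx,cy,radius Adjusted circle; `NULL` keeps the suggestion.
#' @param label Class label.
#' @param image_size Optional `c(width, height)`; when given, the circle
#'   centre is checked to lie inside the image.
#' @return One-row circle tibble with `provenance = "refined"`.
#' @export
refine_proposal <- function(proposal, cx = NULL, cy = NULL, radius = NULL,
                            label = NA_character_, image_size = NULL) {
  sugg <- proposal_circles(proposal)
  cx <- cx %||% sugg$cx
  cy <- cy %||% sugg$cy
  radius <- radius %||% sugg$radius
  if (!is.numeric(radius) || radius <= 0) {
    abort("Refined circle radius must be positive.")
  }
  if (!is.null(image_size) &&
      (cx < 0 || cy < 0 || cx > image_size[1] - 1 || cy > image_size[2] - 1)) {
    abort("Refined circle centre lies outside the image.")
  }
  tibble(image_id = proposal$image_id, cx = cx, cy = cy, radius = radius,
         label = label, provenance = "refined")
}

#' Read / write circle annotations as CSV
#'
#' The circle dialect used throughout: columns `image_id`, `cx`, `cy`,
#' `radius`, `label`, `provenance` (one of proposal/refined/candidate/
#' accepted/truth). Compatible with circle-report exports of annotation
#' tools.
#'
#' @param path CSV path.
#' @return The circle tibble (read) / `path` invisibly (write).
#' @export
read_circles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$image_id <- as.character(df$image_id)
  as_tibble(df)
}

#' @rdname read_circles
#' @param circles Circle tibble.
#' @export
write_circles <- function(circles, path) {
  utils::write.csv(circles, path, row.names = FALSE)
  invisible(path)
}

#' Build 500 x 500 training crops around refined circles
#'
#' For each refined circle a square crop (default 500 px) is cut out of
#' its source image, centred on the circle and shifted inward at borders
#' so the crop stays inside the image (images smaller than the crop size
#' yield smaller crops). All refined circles of the same image whose
#' centre falls inside the crop are carried over, with coordinates
#' translated into the crop frame; they later become the filled-circle
#' object masks of the segmentation training set.
#'
#' @param circles Refined circle tibble.
#' @param manifest Manifest covering the circles' images.
#' @param crop_size Crop edge in pixels (default 500).
#' @param loader Image loader.
#' @return List of `training_sample` objects: each has `crop`
#'   (`h x w x 3` array), `circles` (tibble in crop coordinates),
#'   `source_image_id` and `origin` (`c(x0, y0)` of the crop).
#' @export
make_training_samples <- function(circles, manifest, crop_size = 500L,
                                  loader = load_image) {
  crop_size <- assert_count(crop_size, "crop_size")
  samples <- vector("list", nrow(circles))
  for (id in unique(circles$image_id)) {
    rows <- which(circles$image_id == id)
    pixels <- loader(manifest$path[manifest$id == id])
    H <- dim(pixels)[1]
    W <- dim(pixels)[2]
    cw <- min(crop_size, W)
    ch <- min(crop_size, H)
    for (i in rows) {
      ci <- circles[i, ]
      x0 <- min(max(round(ci$cx) - cw %/% 2L, 0L), W - cw)
      y0 <- min(max(round(ci$cy) - ch %/% 2L, 0L), H - ch)
      inside <- rows[circles$cx[rows] >= x0 & circles$cx[rows] <= x0 + cw - 1 &
                       circles$cy[rows] >= y0 & circles$cy[rows] <= y0 + ch - 1]
      carried <- circles[inside, , drop = FALSE]
      carried$cx <- carried$cx - x0
      carried$cy <- carried$cy - y0
      samples[[i]] <- structure(
        list(crop = pixels[y0 + seq_len(ch), x0 + seq_len(cw), ,
                           drop = FALSE],
             circles = carried, source_image_id = id,
             origin = c(x0 = x0, y0 = y0)),
        class = "training_sample"
      )
    }
  }
  samples
}

#' @export
print.training_sample <- function(x, ...) {
  cat(sprintf("<training_sample> %s @ (%d,%d): %d x %d, %d circle(s)\n",
              x$source_image_id, x$origin[1], x$origin[2],
              ncol(x$crop), nrow(x$crop), nrow(x$circles)))
  invisible(x)
}

# the 8 axis-aligned symmetries, as (quarter-turns, horizontal flip)
dihedral8 <- expand.grid(rot = 0:3, hflip = c(FALSE, TRUE))

# flip/rotate/scale a training sample; circles are transformed consistently.
# Scaling resamples the content about the crop centre on a fixed canvas.
transform_sample <- function(sample, rot = 0L, hflip = FALSE, scale = 1) {
  crop <- sample$crop
  circ <- sample$circles
  H <- dim(crop)[1]
  W <- dim(crop)[2]
  if (hflip) {
    crop <- crop[, W:1, , drop = FALSE]
    circ$cx <- (W - 1) - circ$cx
  }
  for (k in seq_len(rot %% 4L)) {       # 90 deg counter-clockwise
    H2 <- dim(crop)[1]
    W2 <- dim(crop)[2]
    crop <- aperm(crop, c(2L, 1L, 3L))[W2:1, , , drop = FALSE]
    tmp <- circ$cx
    circ$cx <- circ$cy
    circ$cy <- (W2 - 1) - tmp
  }
  if (scale != 1) {
    H3 <- dim(crop)[1]
    W3 <- dim(crop)[2]
    ctr <- c((W3 - 1) / 2, (H3 - 1) / 2)
    src_h <- interp_weights(((seq_len(H3) - 1) - ctr[2]) / scale + ctr[2], H3)
    src_w <- interp_weights(((seq_len(W3) - 1) - ctr[1]) / scale + ctr[1], W3)
    for (ch in 1:3) {
      crop[, , ch] <- src_h %*% crop[, , ch] %*% t(src_w)
    }
    circ$cx <- ctr[1] + scale * (circ$cx - ctr[1])
    circ$cy <- ctr[2] + scale * (circ$cy - ctr[2])
    circ$radius <- circ$radius * scale
  }
  sample$crop <- crop
  sample$circles <- circ
  sample
}

#' Boost a training-sample set by label-preserving augmentation
#'
#' Emits a deterministic stream of augmented sample variants: horizontal/
#' vertical flips and quarter-turn rotations (the 8 axis-aligned
#' symmetries, cycled first), then the same symmetries combined with a
#' mild +/-10% scale jitter. Circle annotations are transformed along with
#' the pixels. With continuous jitter the stream yields far more than
#' `60 * length(samples)` distinct variants.
#'
#' @param samples List of `training_sample` objects.
#' @param factor_target Number of variants to emit.
#' @param seed Integer seed for the scale jitter.
#' @param jitter Half-width of the scale jitter (default 0.1).
#' @return List of `factor_target` augmented `training_sample` objects.
#' @export
boost_training_samples <- function(samples, factor_target, seed = 1L,
                                   jitter = 0.1) {
  if (length(samples) == 0L) {
    abort("Cannot boost an empty training-sample set.")
  }
  factor_target <- assert_count(factor_target, "factor_target")
  set.seed(seed)
  n <- length(samples)
  out <- vector("list", factor_target)
  for (t in seq_len(factor_target)) {
    j <- ((t - 1L) %% n) + 1L
    round <- (t - 1L) %/% n
    d <- dihedral8[(round %% 8L) + 1L, ]
    scale <- if (round < 8L) 1 else runif(1, 1 - jitter, 1 + jitter)
    out[[t]] <- transform_sample(samples[[j]], rot = d$rot,
                                 hflip = d$hflip, scale = scale)
  }
  out
}

#' Pad an image so both dimensions are divisible by 64
#'
#' Zero-pads on the right and bottom only, so original pixel coordinates
#' stay valid in the padded frame (required by segmentation backends with
#' pyramid downscaling). `unpad_image()` restores the original extent.
#'
#' @param pixels `H x W x 3` array (or a single-channel matrix).
#' @param multiple Divisibility requirement (default 64).
#' @return A `padded_image`: list with `pixels` and the original `width`,
#'   `height`.
#' @export
pad_to_multiple_64 <- function(pixels, multiple = 64L) {
  multiple <- assert_count(multiple, "multiple")
  d <- dim(pixels)
  H <- d[1]
  W <- d[2]
  H2 <- as.integer(ceiling(H / multiple) * multiple)
  W2 <- as.integer(ceiling(W / multiple) * multiple)
  if (length(d) == 3L) {
    out <- array(0, dim = c(H2, W2, d[3]))
    out[seq_len(H), seq_len(W), ] <- pixels
  } else {
    out <- matrix(0, H2, W2)
    out[seq_len(H), seq_len(W)] <- pixels
  }
  structure(list(pixels = out, width = W, height = H),
            class = "padded_image")
}

#' @rdname pad_to_multiple_64
#' @param padded A `padded_image` (or any list with `pixels`, `width`,
#'   `height`), possibly with its `pixels` replaced by a backend's mask of
#'   the same padded shape.
#' @export
unpad_image <- function(padded) {
  p <- padded$pixels
  if (length(dim(p)) == 3L) {
    p[seq_len(padded$height), seq_len(padded$width), , drop = FALSE]
  } else {
    p[seq_len(padded$height), seq_len(padded$width), drop = FALSE]
  }
}

#' Minimum enclosing circle of a point set
#'
#' Exact smallest circle containing all points, computed by Welzl's
#' recursion on the convex hull (the hull keeps the recursion small for
#' pixel regions of any size).
#'
#' @param pts Numeric matrix `n x 2` of (x, y) coordinates.
#' @return List with `cx`, `cy`, `radius`.
#' @export
min_enclosing_circle <- function(pts) {
  pts <- unique(matrix(as.numeric(pts), ncol = 2L,
                       dimnames = list(NULL, c("x", "y"))))
  dimnames(pts) <- NULL
  n <- nrow(pts)
  if (n == 0L) abort("Need at least one point.")
  if (n == 1L) return(list(cx = pts[1, 1], cy = pts[1, 2], radius = 0))
  if (n > 3L) {
    hull <- grDevices::chull(pts[, 1], pts[, 2])
    pts <- pts[hull, , drop = FALSE]
    n <- nrow(pts)
    # deterministic pseudo-shuffle keeps Welzl's recursion shallow even
    # though hull points are in convex position
    pts <- pts[order(sin(seq_len(n) * 12.9898) * 43758.5453 %% 1), ,
               drop = FALSE]
  }
  circ <- unname(welzl(pts, matrix(numeric(0), 0, 2)))
  list(cx = circ[1], cy = circ[2], radius = circ[3])
}

# circle through <= 3 boundary points
circle_of <- function(b) {
  if (nrow(b) == 0L) return(c(0, 0, -1))
  if (nrow(b) == 1L) return(c(b[1, ], 0))
  if (nrow(b) == 2L) {
    c((b[1, ] + b[2, ]) / 2, sqrt(sum((b[1, ] - b[2, ])^2)) / 2)
  } else {
    ax <- b[1, 1]; ay <- b[1, 2]
    bx <- b[2, 1]; by <- b[2, 2]
    cx <- b[3, 1]; cy <- b[3, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) {              # collinear: span the farthest pair
      dd <- as.matrix(stats::dist(b))
      ij <- which(dd == max(dd), arr.ind = TRUE)[1, ]
      return(circle_of(b[ij, , drop = FALSE]))
    }
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
}

in_circle <- function(circ, p) {
  circ[3] >= 0 &&
    sqrt((p[1] - circ[1])^2 + (p[2] - circ[2])^2) <=
      circ[3] * (1 + 1e-10) + 1e-12
}

welzl <- function(p, b) {
  if (nrow(p) == 0L || nrow(b) == 3L) return(circle_of(b))
  q <- p[nrow(p), , drop = FALSE]
  circ <- welzl(p[-nrow(p), , drop = FALSE], b)
  if (in_circle(circ, q[1, ])) return(circ)
  welzl(p[-nrow(p), , drop = FALSE], rbind(b, q))
}

#' Convert a segmentation mask to circle annotation candidates
#'
#' Any pixel with a nonzero class id is "interesting"; 8-connected regions
#' of interesting pixels (classes are merged, the segmentation is treated
#' as class-agnostic) each yield the minimum enclosing circle of their
#' pixel centres. Radii are floored at 0.5 px so single-pixel regions
#' remain displayable.
#'
#' @param mask Integer `H x W` matrix of class ids, 0 = background.
#' @param image_id Identifier stored on the candidates.
#' @return Circle tibble with `provenance = "candidate"`; `label` is the
#'   modal nonzero class id (as character) of the region's pixels.
#' @export
masks_to_candidates <- function(mask, image_id = NA_character_) {
  if (!is.matrix(mask)) abort("`mask` must be an integer matrix.")
  labels <- extract_regions(mask != 0)
  n <- max(labels)
  if (n == 0L) {
    return(tibble(image_id = character(), cx = numeric(), cy = numeric(),
                  radius = numeric(), label = character(),
                  provenance = character(), region_id = integer()))
  }
  H <- nrow(mask)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  px <- (idx - 1L) %/% H
  py <- (idx - 1L) %% H
  cls <- mask[idx]
  out <- lapply(seq_len(n), function(j) {
    sel <- lab == j
    mec <- min_enclosing_circle(cbind(px[sel], py[sel]))
    counts <- table(cls[sel])
    tibble(image_id = image_id, cx = mec$cx, cy = mec$cy,
           radius = max(0.5, mec$radius),
           label = names(counts)[which.max(counts)],
           provenance = "candidate", region_id = j)
  })
  dplyr::bind_rows(out)
}

#' Apply accept/reject review decisions to annotation candidates
#'
#' The final human pass: keep the candidates marked as true positives.
#'
#' @param candidates Candidate circle tibble (with `region_id`).
#' @param accept Tibble with columns `image_id`, `region_id` naming the
#'   accepted candidates.
#' @return Accepted circles with `provenance = "accepted"` and attribute
#'   `"class_counts"`.
#' @export
review_candidates <- function(candidates, accept) {
  key <- function(df) paste(df$image_id, df$region_id, sep = "\r")
  miss <- !(key(accept) %in% key(candidates))
  if (any(miss)) {
    abort(sprintf("Unknown candidate id(s): %s",
                  paste(accept$image_id[miss], accept$region_id[miss],
                        sep = "/", collapse = ", ")))
  }
  out <- candidates[key(candidates) %in% key(accept), , drop = FALSE]
  out$provenance <- "accepted"
  attr(out, "class_counts") <- dplyr::count(out, .data$label,
                                            name = "n_accepted")
  out
}

#' Trivial segmentation backends
#'
#' The instance-segmentation network is pluggable: a backend is any
#' function mapping an `H x W x 3` pixel array to an integer `H x W`
#' class-id mask (0 = background) of the same shape. `threshold_backend()`
#' marks pixels whose chosen channel exceeds a threshold — enough to
#' exercise the full candidate pipeline without a network.
#' `oracle_backend()` renders ground-truth circles as filled disks, for
#' testing the post-processing in isolation. An external network can be
#' dropped in as a function reading/writing image and mask files.
#'
#' @param channel Channel index 1-3.
#' @param threshold Intensity threshold in `[0, 1]`.
#' @return A backend function.
#' @export
threshold_backend <- function(channel = 1L, threshold = 0.5) {
  force(channel); force(threshold)
  function(pixels) {
    (pixels[, , channel] > threshold) * 1L
  }
}

#' @rdname threshold_backend
#' @param truth Circle tibble for one image (`cx`, `cy`, `radius`,
#'   `label`); labels are mapped to class ids 1, 2, ... in sorted order.
#' @export
oracle_backend <- function(truth) {
  force(truth)
  function(pixels) {
    H <- dim(pixels)[1]
    W <- dim(pixels)[2]
    mask <- matrix(0L, H, W)
    ids <- match(truth$label, sort(unique(truth$label)))
    xs <- matrix(rep(0:(W - 1), each = H), H, W)
    ys <- matrix(rep(0:(H - 1), W), H, W)
    for (i in seq_len(nrow(truth))) {
      inside <- (xs - truth$cx[i])^2 + (ys - truth$cy[i])^2 <=
        truth$radius[i]^2
      mask[inside] <- ids[i]
    }
    mask
  }
}

#' Run a segmentation backend and extract annotation candidates
#'
#' Stage III inference plumbing: pad the image to multiples of 64, run the
#' backend, verify the mask shape, unpad, and convert connected
#' interesting regions to minimum-enclosing-circle candidates.
#'
#' @param pixels `H x W x 3` array.
#' @param backend A backend function (see [threshold_backend()]).
#' @param image_id Identifier for the emitted candidates.
#' @return Candidate circle tibble.
#' @export
detect_candidates <- function(pixels, backend, image_id = NA_character_) {
  padded <- pad_to_multiple_64(pixels)
  mask <- backend(padded$pixels)
  if (!identical(dim(mask), dim(padded$pixels)[1:2])) {
    abort("Backend mask shape must equal the padded input shape.")
  }
  padded$pixels <- mask
  masks_to_candidates(unpad_image(padded), image_id = image_id)
}
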