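ranked_fixture <- function(n, labels = NULL) {
  r <- tibble::tibble(
    image_id = "img",
    x = 0L, y = 0L, edge = 30L,
    score = rev(seq_len(n)) * 1.0,
    region_id = seq_len(n)
  )
  rank_proposals(r)
}

test_that("filtering honours the per-class limit and prefix rule", {
  ranked <- ranked_fixture(700)
  dec <- tibble::tibble(image_id = "img", region_id = 1:700,
                        label = "shell")
  acc <- filter_proposals(ranked, dec, per_class_limit = 600)
  expect_equal(nrow(acc), 600L)
  expect_equal(acc$region_id, 1:600)            # kept in rank order
  expect_equal(attr(acc, "class_counts")$n_accepted, 600L)

  # all rejected -> empty set
  rej <- dplyr::mutate(dec, label = NA_character_)
  expect_equal(nrow(filter_proposals(ranked, rej)), 0L)

  # two classes count independently (one saturates, one does not)
  dec2 <- tibble::tibble(image_id = "img", region_id = 1:700,
                         label = rep(c("shell", "animal"), c(650, 50)))
  acc2 <- filter_proposals(ranked, dec2, per_class_limit = 600)
  counts <- attr(acc2, "class_counts")
  expect_equal(sort(counts$n_accepted), c(50L, 600L))

  bad <- tibble::tibble(image_id = "img", region_id = 9999L, label = "x")
  expect_error(filter_proposals(ranked, bad), "unknown")
  gap <- tibble::tibble(image_id = "img", region_id = c(1L, 3L),
                        label = "x")                 # rank 2 skipped
  expect_error(filter_proposals(ranked, gap), "prefix")
})

test_that("the default refinement circle is the proposal's inscribed circle", {
  p <- tibble::tibble(image_id = "img", x = 100L, y = 100L, edge = 30L,
                      score = 1, region_id = 1L)
  circ <- refine_proposal(p, label = "animal")
  expect_equal(circ$cx, 114.5)
  expect_equal(circ$cy, 114.5)
  expect_equal(circ$radius, 15)
  expect_equal(circ$provenance, "refined")

  adj <- refine_proposal(p, radius = 12, label = "animal")
  expect_equal(adj$radius, 12)
  expect_error(refine_proposal(p, radius = -1), "positive")
  expect_error(refine_proposal(p, cx = 5000, image_size = c(200, 200)),
               "outside")
})

test_that("training crops are centred, border-shifted, and carry nearby circles", {
  imgs <- list(big = const_image(600, 700, c(0.3, 0.3, 0.3)))
  man <- mem_manifest(imgs)
  circles <- tibble::tibble(
    image_id = "big",
    cx = c(350, 10, 360), cy = c(300, 10, 310),
    radius = c(20, 5, 8), label = "animal", provenance = "refined"
  )
  samples <- make_training_samples(circles, man, crop_size = 500,
                                   loader = mem_loader(imgs))
  expect_length(samples, 3L)
  s1 <- samples[[1]]
  expect_equal(dim(s1$crop), c(500L, 500L, 3L))
  expect_equal(s1$circles$cx[1], 250)              # centred crop
  expect_equal(s1$circles$cy[1], 250)
  expect_equal(nrow(s1$circles), 2L)               # circle 3 carried over
  expect_true(8 %in% s1$circles$radius)

  s2 <- samples[[2]]
  expect_equal(unname(s2$origin), c(0L, 0L))       # shifted inward at border
  expect_equal(s2$circles$cx[s2$circles$radius == 5], 10)

  # image smaller than the crop: crop shrinks to the image
  small <- list(s = const_image(200, 900, c(0.1, 0.2, 0.3)))
  sman <- mem_manifest(small)
  ss <- make_training_samples(tibble::tibble(
    image_id = "s", cx = 450, cy = 100, radius = 10, label = "a",
    provenance = "refined"), sman, loader = mem_loader(small))
  expect_equal(dim(ss[[1]]$crop), c(200L, 500L, 3L))
})

test_that("boosting cycles the 8 axis-aligned symmetries with exact circle transforms", {
  crop <- array(0.2, dim = c(500, 500, 3))
  sample <- structure(
    list(crop = crop,
         circles = tibble::tibble(image_id = "i", cx = 100, cy = 40,
                                  radius = 10, label = "a",
                                  provenance = "refined"),
         source_image_id = "i", origin = c(x0 = 0, y0 = 0)),
    class = "training_sample")

  v8 <- boost_training_samples(list(sample), 8, seed = 1)
  keys <- vapply(v8, function(s) paste(round(s$circles$cx, 3),
                                       round(s$circles$cy, 3)), character(1))
  expect_equal(length(unique(keys)), 8L)           # 8 distinct symmetries

  # horizontal flip of a 500-wide crop: x -> (W-1) - x
  flipped <- benthoscan:::transform_sample(sample, hflip = TRUE)
  expect_equal(flipped$circles$cx, 399)
  expect_equal(flipped$circles$cy, 40)

  # determinism of the jittered tail of the stream
  a <- boost_training_samples(list(sample), 20, seed = 9)
  b <- boost_training_samples(list(sample), 20, seed = 9)
  expect_equal(vapply(a, function(s) s$circles$radius, numeric(1)),
               vapply(b, function(s) s$circles$radius, numeric(1)))
  expect_error(boost_training_samples(list(), 5), "empty")
})

test_that("augmentation keeps circles on their objects (pixel IoU)", {
  crop <- array(0, dim = c(300, 300, 3))
  disk_mask <- function(H, W, cx, cy, r) {
    xs <- matrix(rep(0:(W - 1), each = H), H, W)
    ys <- matrix(rep(0:(H - 1), W), H, W)
    (xs - cx)^2 + (ys - cy)^2 <= r^2
  }
  m0 <- disk_mask(300, 300, 120, 90, 25)
  for (ch in 1:3) crop[, , ch][m0] <- 1
  sample <- structure(
    list(crop = crop,
         circles = tibble::tibble(image_id = "i", cx = 120, cy = 90,
                                  radius = 25, label = "a",
                                  provenance = "refined"),
         source_image_id = "i", origin = c(x0 = 0, y0 = 0)),
    class = "training_sample")
  for (tf in list(list(rot = 1L, hflip = FALSE, scale = 1),
                  list(rot = 2L, hflip = TRUE, scale = 1),
                  list(rot = 0L, hflip = FALSE, scale = 0.92),
                  list(rot = 3L, hflip = TRUE, scale = 1.08))) {
    tr <- benthoscan:::transform_sample(sample, rot = tf$rot,
                                        hflip = tf$hflip, scale = tf$scale)
    got <- tr$crop[, , 1] > 0.5
    want <- disk_mask(dim(tr$crop)[1], dim(tr$crop)[2],
                      tr$circles$cx, tr$circles$cy, tr$circles$radius)
    iou <- sum(got & want) / sum(got | want)
    expect_gte(iou, 0.95)
  }
})

test_that("padding to multiples of 64 is right/bottom-only and reversible", {
  img <- noise_image(2048, 2448, seed = 1)          # 2448 wide, 2048 high
  p <- pad_to_multiple_64(img)
  expect_equal(dim(p$pixels), c(2048L, 2496L, 3L))  # ceil(2448/64) * 64
  expect_identical(unpad_image(p), img)
  expect_equal(p$pixels[1, 1, ], img[1, 1, ])       # origin preserved

  ok <- pad_to_multiple_64(const_image(64, 64))
  expect_equal(dim(ok$pixels), c(64L, 64L, 3L))     # already divisible

  tiny <- pad_to_multiple_64(matrix(7, 1, 1))
  expect_equal(dim(tiny$pixels), c(64L, 64L))
  expect_equal(tiny$pixels[1, 1], 7)
  expect_equal(sum(tiny$pixels), 7)                 # zero padding
})

test_that("minimum enclosing circles are exact", {
  # single pixel
  expect_equal(min_enclosing_circle(cbind(5, 7)),
               list(cx = 5, cy = 7, radius = 0))
  # 3x3 pixel square: centre pixel, radius sqrt(2)
  grid9 <- as.matrix(expand.grid(x = 0:2, y = 0:2))
  mec <- min_enclosing_circle(grid9)
  expect_equal(mec$cx, 1)
  expect_equal(mec$cy, 1)
  expect_equal(mec$radius, sqrt(2))

  # brute-force oracle over all pairs and triples on random small regions
  brute_mec <- function(pts) {
    n <- nrow(pts)
    best <- NULL
    check <- function(c3) {
      d <- sqrt((pts[, 1] - c3[1])^2 + (pts[, 2] - c3[2])^2)
      if (all(d <= c3[3] + 1e-9) &&
          (is.null(best) || c3[3] < best[3] - 1e-12)) best <<- c3
    }
    for (i in 1:n) for (j in i:n) {
      m <- (pts[i, ] + pts[j, ]) / 2
      check(c(m, sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2))
    }
    if (n >= 3) {
      for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
        c3 <- benthoscan:::circle_of(pts[c(i, j, k), , drop = FALSE])
        check(c3)
      }
    }
    best
  }
  set.seed(8)
  for (rep in 1:10) {
    pts <- unique(cbind(sample(0:9, 15, TRUE), sample(0:9, 15, TRUE)))
    pts <- pts[seq_len(min(nrow(pts), 25)), , drop = FALSE]
    got <- min_enclosing_circle(pts)
    want <- brute_mec(pts)
    expect_equal(got$radius, want[3], tolerance = 1e-7)
    d <- sqrt((pts[, 1] - got$cx)^2 + (pts[, 2] - got$cy)^2)
    expect_true(all(d <= got$radius + 1e-7))
  }
})

test_that("segmentation masks become class-agnostic circle candidates", {
  mask <- matrix(0L, 20, 20)
  mask[3, 4] <- 1L                                  # single pixel
  mask[10:12, 10:12] <- 1L                          # 3x3 square
  mask[12:14, 13:15] <- 2L                          # touches the square
  cands <- masks_to_candidates(mask, image_id = "m")
  expect_equal(nrow(cands), 2L)                     # classes merged
  single <- cands[cands$radius == 0.5, ]
  expect_equal(single$cx, 3)                        # 0-based x = col - 1
  expect_equal(single$cy, 2)
  expect_true(all(cands$provenance == "candidate"))

  only9 <- matrix(0L, 10, 10)
  only9[4:6, 5:7] <- 3L
  c9 <- masks_to_candidates(only9, "m")
  expect_equal(c9$radius, sqrt(2))
  expect_equal(c9$label, "3")

  empty <- masks_to_candidates(matrix(0L, 5, 5), "m")
  expect_equal(nrow(empty), 0L)
})

test_that("candidate review keeps exactly the accepted true positives", {
  cands <- tibble::tibble(
    image_id = rep("v", 501), cx = runif(501, 10, 90),
    cy = runif(501, 10, 90), radius = 5,
    label = "interesting", provenance = "candidate", region_id = 1:501
  )
  accept <- tibble::tibble(image_id = "v", region_id = sort(sample(501, 276)))
  a <- review_candidates(cands, accept)
  expect_equal(nrow(a), 276L)
  expect_true(all(a$provenance == "accepted"))

  none <- review_candidates(cands, accept[0, ])
  expect_equal(nrow(none), 0L)

  all_acc <- review_candidates(cands,
                               tibble::tibble(image_id = "v", region_id = 1:501))
  again <- review_candidates(all_acc,
                             tibble::tibble(image_id = "v", region_id = 1:501))
  expect_equal(nrow(again), 501L)                   # accept-all idempotent

  expect_error(review_candidates(cands, tibble::tibble(image_id = "v",
                                                       region_id = 999L)),
               "Unknown")
})

test_that("the padded-inference plumbing works with trivial backends", {
  img <- const_image(70, 90, c(0.1, 0.1, 0.1))
  img[30:40, 50:60, 1] <- 0.9                       # bright patch on channel 1
  cands <- detect_candidates(img, threshold_backend(channel = 1,
                                                    threshold = 0.5), "img")
  expect_equal(nrow(cands), 1L)
  expect_true(cands$cx >= 49 && cands$cx <= 60)

  truth <- tibble::tibble(image_id = "img", cx = 20, cy = 20, radius = 6,
                          label = "animal")
  oc <- detect_candidates(img, oracle_backend(truth), "img")
  expect_equal(nrow(oc), 1L)
  expect_equal(oc$cx, 20, tolerance = 1)
  expect_equal(oc$radius, 6, tolerance = 1)

  bad_backend <- function(pixels) matrix(0L, 2, 2)
  expect_error(detect_candidates(img, bad_backend), "shape")
})
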