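test_that("F2 weights recall twice as heavily and handles the zero case", {
  # the published validation pairs reproduce the published scores
  expect_equal(round(100 * f2_score(0.917, 0.505), 1), 78.8)
  expect_equal(round(100 * f2_score(0.772, 0.143), 1), 41.1)
  expect_equal(round(100 * f2_score(0.834, 0.261), 1), 58.0)
  expect_equal(f2_score(1, 1), 1)
  expect_equal(f2_score(0, 0), 0)
  expect_error(f2_score(1.2, 0.5), "\\[0, 1\\]")

  # equals the general F-beta formula at beta = 2 over a grid
  fbeta <- function(r, p, beta) (1 + beta^2) * p * r / (beta^2 * p + r)
  grid <- expand.grid(r = seq(0.05, 1, by = 0.05), p = seq(0.05, 1, by = 0.05))
  expect_equal(f2_score(grid$r, grid$p), fbeta(grid$r, grid$p, 2),
               tolerance = 1e-15)
})

test_that("containment counting distinguishes object-side and region-side truth", {
  regions <- tibble::tibble(image_id = c("a", "a"),
                            x = c(0L, 50L), y = c(0L, 50L), edge = 30L)
  truth <- tibble::tibble(image_id = "a", cx = c(5, 20), cy = c(5, 20),
                          label = "animal")
  ev <- match_detections(regions, truth)
  expect_equal(ev$tp_theta, 2L)       # one region holds both objects
  expect_equal(ev$fn_theta, 0L)
  expect_equal(ev$tp_rho, 1L)
  expect_equal(ev$fp_rho, 1L)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$f2, f2_score(1, 0.5))

  none <- match_detections(regions[0, ], truth)
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 0)
  expect_false(none$precision_defined)

  g <- glance(ev)
  expect_equal(g$tp_rho, 1L)
  t <- tidy(ev)
  expect_equal(t$value[t$metric == "recall"], 1)
})

test_that("containment counting matches a brute-force oracle on random cases", {
  set.seed(21)
  for (rep in 1:15) {
    nr <- sample(0:6, 1)
    nt <- sample(1:8, 1)
    regions <- tibble::tibble(
      image_id = sample(c("a", "b"), nr, TRUE),
      x = sample(0:60, nr, TRUE), y = sample(0:60, nr, TRUE),
      edge = sample(c(10L, 30L), nr, TRUE))
    truth <- tibble::tibble(
      image_id = sample(c("a", "b"), nt, TRUE),
      cx = runif(nt, 0, 90), cy = runif(nt, 0, 90), label = "x")
    ev <- match_detections(regions, truth)
    inside <- function(t, r) {
      t$image_id == r$image_id &&
        t$cx >= r$x && t$cx <= r$x + r$edge - 1 &&
        t$cy >= r$y && t$cy <= r$y + r$edge - 1
    }
    hits <- matrix(FALSE, nt, max(nr, 1))
    for (i in seq_len(nt)) for (j in seq_len(nr)) {
      hits[i, j] <- inside(truth[i, ], regions[j, ])
    }
    expect_equal(ev$tp_theta, sum(apply(hits, 1, any)))
    expect_equal(ev$fn_theta, nt - sum(apply(hits, 1, any)))
    if (nr > 0) {
      expect_equal(ev$tp_rho, sum(apply(hits, 2, any)[seq_len(nr)]))
      expect_equal(ev$fp_rho, nr - ev$tp_rho)
    }
    # invariance to region order
    if (nr > 1) {
      ev2 <- match_detections(regions[sample(nr), ], truth)
      expect_equal(glance(ev2), glance(ev))
    }
  }
})

test_that("the annotation-time model reproduces its closed forms", {
  p <- time_model_params()
  expect_equal(tau_maia(0, p), 12327)
  expect_equal(tau_maia(550, p), 18.34 * 550 + 12327)
  expect_equal(tau_trad(0, p), 0)
  expect_equal(tau_trad(550, p), 49098.5)
  # linearity / proportionality
  n <- c(10, 100, 400)
  expect_equal(tau_maia(2 * n, p) - tau_maia(n, p), p$review_rate * n)
  expect_equal(tau_trad(2 * n, p), 2 * tau_trad(n, p))
  expect_error(tau_maia(-1, p), "nonnegative")

  sb <- speedup_and_breakeven(p)
  expect_equal(round(sb$speedup(550), 2), 2.19)
  expect_equal(sb$breakeven, 12327 / (89.27 - 18.34))
  expect_lt(sb$breakeven, 200)
  # exact crossover: assisted faster iff n > n*
  expect_lt(tau_maia(sb$breakeven + 1, p), tau_trad(sb$breakeven + 1, p))
  expect_gt(tau_maia(sb$breakeven - 1, p), tau_trad(sb$breakeven - 1, p))
  # speed-up grows with the dataset
  s <- sb$speedup(c(50, 200, 550, 5000))
  expect_true(all(diff(s) > 0))

  flat <- time_model_params(review_rate = 90, trad_rate = 89.27)
  expect_warning(sbf <- speedup_and_breakeven(flat), "no crossover")
  expect_false(sbf$crossover_exists)

  curves <- time_model_curves(p, n_max = 100, by = 50)
  expect_equal(curves$n, c(0, 50, 100))
  expect_equal(curves$tau_manual, tau_trad(curves$n, p))
})

test_that("the time model refit from the published sessions matches the defaults", {
  sessions <- published_annotation_sessions()
  fit <- fit_time_model(sessions, training_images = 500)
  expect_equal(round(fit$review_rate, 2), 18.34)
  expect_equal(round(fit$setup_cost), 12327)
  expect_equal(round(fit$trad_rate, 2), 89.27)
  per <- attr(fit, "per_dataset")
  expect_equal(round(per$prep_s_per_image, 2), c(14.54, 54.02, 5.39))
  expect_equal(round(mean(per$prep_s_per_image), 2), 24.65)
})

test_that("the parameter search tabulates one row per triplet, reproducibly", {
  imgs <- setNames(lapply(1:4, function(i) noise_image(48, 48, seed = 30 + i)),
                   paste0("i", 1:4))
  # plant one bright object per image so truth is non-trivial
  truth <- dplyr::bind_rows(lapply(1:4, function(i) {
    tibble::tibble(image_id = paste0("i", i), cx = 10 * i, cy = 10 * i,
                   radius = 3, label = "a")
  }))
  for (i in 1:4) imgs[[i]][10 * i + (0:3), 10 * i + (0:3), ] <- 0.99
  man <- mem_manifest(imgs)
  grid <- tibble::tibble(K = c(1L, 2L), patch_edge = c(7L, 7L),
                         compression = c(0.1, 0.1))
  cfg <- tiny_config(patch_edge = 7L, epochs = 3L, n_train_patches = 100L)
  res1 <- parameter_search(man, truth, grid = grid, config = cfg, seed = 5,
                           loader = mem_loader(imgs), min_edge = 10L)
  expect_equal(nrow(res1), 2L)
  expect_true(all(c("recall", "precision", "f2") %in% names(res1)))
  res2 <- parameter_search(man, truth, grid = grid, config = cfg, seed = 5,
                           loader = mem_loader(imgs), min_edge = 10L)
  expect_identical(res1, res2)
})
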