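test_that("configuration derives the latent size from the compression factor", {
  cfg <- aen_config()                       # published defaults
  expect_equal(cfg$input_dim, 3 * 39^2)     # r = 4563
  expect_equal(cfg$latent_dim, 456L)        # s = round(0.1 * r)
  expect_equal(aen_config(patch_edge = 29)$input_dim, 2523L)
  expect_error(aen_config(patch_edge = 40), "odd")
  expect_error(aen_config(compression = 1.2), "between 0 and 1")
  expect_error(aen_config(compression = 0), "between 0 and 1")
})

test_that("softplus matches its closed forms and is overflow-safe", {
  expect_equal(softplus(0), log(2))
  expect_equal(softplus(100), 100, tolerance = 1e-12)
  expect_equal(softplus(-100), exp(-100), tolerance = 1e-6)
  expect_true(softplus(-100) > 0)
  expect_true(all(is.finite(softplus(c(-1e6, 0, 1e6)))))
  m <- matrix(c(-1, 0, 1, 2), 2, 2)
  expect_equal(dim(softplus(m)), dim(m))
})

test_that("encode/decode implement the softplus layers with shape checks", {
  cfg <- tiny_config()
  r <- cfg$input_dim
  s <- cfg$latent_dim
  dbm0 <- benthoscan:::new_dbm(matrix(0, s, r), rep(0, s),
                               matrix(0, r, s), rep(0, r), cfg)
  x <- runif(r)
  l <- encode(x, dbm0)
  expect_equal(as.vector(l), rep(log(2), s))   # W = 0, b = 0
  expect_equal(as.vector(decode(l, dbm0)), rep(log(2), r))
  expect_identical(encode(x, dbm0), encode(x, dbm0))
  expect_true(all(is.finite(decode(encode(x, dbm0), dbm0))))
  expect_error(encode(runif(r + 1), dbm0), "components")
  expect_error(decode(runif(s + 2), dbm0), "components")
})

test_that("reconstruction error is the summed squared difference", {
  expect_equal(reconstruction_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(reconstruction_error(c(0, 0), c(1, 1)), 2)
  x <- runif(20); y <- runif(20); c <- 3.7
  expect_equal(reconstruction_error(c * x, c * y),
               c^2 * reconstruction_error(x, y))   # homogeneity
  expect_error(reconstruction_error(1:3, 1:4), "identical dimensions")
  # matrix form: one error per column
  xm <- matrix(runif(10), 5); ym <- matrix(runif(10), 5)
  expect_equal(reconstruction_error(xm, ym),
               c(sum((xm[, 1] - ym[, 1])^2), sum((xm[, 2] - ym[, 2])^2)))
})

test_that("training reduces the error, learns constants, and is bit-reproducible", {
  imgs <- list(bg = noise_image(48, 48, seed = 7, base = 0.5, sd = 0.03))
  man <- mem_manifest(imgs)
  cfg <- tiny_config()
  fit1 <- train_dbm(man, cfg, loader = mem_loader(imgs))
  expect_lt(tail(fit1$epoch_loss, 1), fit1$epoch_loss[1])   # descent
  fit2 <- train_dbm(man, cfg, loader = mem_loader(imgs))
  expect_identical(fit1$W, fit2$W)                          # same seed
  expect_identical(fit1$b_dec, fit2$b_dec)

  # constant-colour cluster is trivially learnable
  cimgs <- list(flat = const_image(40, 40, c(0.4, 0.5, 0.6)))
  cman <- mem_manifest(cimgs)
  cfit <- train_dbm(cman, tiny_config(epochs = 60L),
                    loader = mem_loader(cimgs))
  expect_lt(tail(cfit$epoch_loss, 1), 0.05)

  expect_error(train_dbm(man[0, ], cfg), "empty")
})

test_that("a trained model scores unfamiliar patches higher than background", {
  imgs <- list(bg = noise_image(64, 64, seed = 11, base = 0.45, sd = 0.04))
  man <- mem_manifest(imgs)
  dbm <- train_dbm(man, tiny_config(epochs = 30L), loader = mem_loader(imgs))
  e <- dbm$config$patch_edge
  bg_patch <- extract_patches(imgs$bg, 20L, 20L, e)
  obj_patch <- matrix(rep(c(0.98, 0.98, 0.95), e^2), ncol = 1)  # white object
  f_bg <- reconstruction_error(bg_patch, decode(encode(bg_patch, dbm), dbm))
  f_obj <- reconstruction_error(obj_patch, decode(encode(obj_patch, dbm), dbm))
  expect_gt(f_obj, f_bg)
})

test_that("convolutional application matches per-patch encode/decode and slicing", {
  imgs <- list(bg = noise_image(40, 46, seed = 13))
  man <- mem_manifest(imgs)
  cfg <- tiny_config(patch_edge = 7L, epochs = 5L, n_train_patches = 100L)
  dbm <- train_dbm(man, cfg, loader = mem_loader(imgs))
  nm <- apply_dbm(imgs$bg, dbm, stride = 2, image_id = "bg")
  expect_equal(dim(nm$values), c(40L, 46L))                # full image shape
  expect_false(nm$dilated)
  expect_true(all(nm$values >= 0))

  # exact agreement with the direct path at a few grid centres
  for (c_xy in list(c(3L, 3L), c(9L, 7L), c(21L, 15L))) {
    x <- extract_patches(imgs$bg, c_xy[1], c_xy[2], 7L)
    f <- reconstruction_error(x[, 1], decode(encode(x[, 1], dbm), dbm)[, 1])
    expect_equal(nm$values[c_xy[2] + 1, c_xy[1] + 1], f, tolerance = 1e-12)
  }

  # horizontal slicing does not change the result
  dbm1 <- dbm
  dbm1$config$slice_rows <- 1L
  nm1 <- apply_dbm(imgs$bg, dbm1, stride = 2)
  expect_identical(nm1$values, nm$values)

  # stride 1 and stride 2 agree exactly on the shared grid centres
  nmA <- apply_dbm(imgs$bg, dbm, stride = 1)
  g2 <- patch_grid(46, 40, 7L, 2L)
  expect_equal(nmA$values[cbind(g2$cy + 1, g2$cx + 1)],
               nm$values[cbind(g2$cy + 1, g2$cx + 1)], tolerance = 1e-12)

  expect_error(apply_dbm(const_image(5, 5), dbm), "smaller")
})

test_that("application is translation-consistent at the stride", {
  imgs <- list(bg = noise_image(30, 36, seed = 17))
  man <- mem_manifest(imgs)
  cfg <- tiny_config(patch_edge = 5L, epochs = 5L, n_train_patches = 100L)
  dbm <- train_dbm(man, cfg, loader = mem_loader(imgs))
  stride <- 2L
  shifted <- imgs$bg[, -(1:stride), , drop = FALSE]        # shift left by one cell
  nm0 <- apply_dbm(imgs$bg, dbm, stride = stride)
  nm1 <- apply_dbm(shifted, dbm, stride = stride)
  g <- patch_grid(dim(shifted)[2], dim(shifted)[1], 5L, stride)
  expect_equal(nm1$values[cbind(g$cy + 1, g$cx + 1)],
               nm0$values[cbind(g$cy + 1, g$cx + stride + 1)],
               tolerance = 1e-12)
})

test_that("a constant image under a constant-trained model is near-zero novelty", {
  cimgs <- list(flat = const_image(30, 30, c(0.4, 0.5, 0.6)))
  cman <- mem_manifest(cimgs)
  dbm <- train_dbm(cman, tiny_config(patch_edge = 5L, epochs = 60L),
                   loader = mem_loader(cimgs))
  nm <- apply_dbm(cimgs$flat, dbm)
  expect_lt(max(nm$values), 0.05)
})

test_that("dilation is an exact all-ones convolution with zero padding", {
  v <- 2.5
  m <- matrix(0, 21, 23)
  m[11, 12] <- v                                           # interior impulse
  nm <- make_nm(m, dilated = FALSE, patch_edge = 5L)
  d <- dilate_novelty_map(nm, kernel_edge = 5L)
  expect_true(d$dilated)
  expect_equal(sum(d$values), v * 25)                      # mass = v * k^2
  expect_equal(sum(d$values == v), 25)                     # a 5x5 square of v
  expect_equal(d$values[11, 12], v)

  z <- dilate_novelty_map(make_nm(matrix(0, 8, 8), dilated = FALSE))
  expect_true(all(z$values == 0))
  expect_error(dilate_novelty_map(nm, kernel_edge = 4L), "odd")
})

test_that("background models and novelty maps survive serialisation", {
  imgs <- list(bg = noise_image(30, 30, seed = 19))
  man <- mem_manifest(imgs)
  dbm <- train_dbm(man, tiny_config(patch_edge = 5L, epochs = 3L,
                                    n_train_patches = 80L),
                   loader = mem_loader(imgs))
  f <- withr::local_tempfile(fileext = ".json")
  write_dbm(dbm, f)
  back <- read_dbm(f)
  expect_equal(back$W, dbm$W)
  expect_equal(back$b_dec, dbm$b_dec)
  x <- runif(dbm$config$input_dim)
  expect_equal(encode(x, back), encode(x, dbm))

  nm <- apply_dbm(imgs$bg, dbm, image_id = "bg")
  tf <- withr::local_tempfile(fileext = ".tif")
  write_novelty_map(nm, tf)
  nm2 <- read_novelty_map(tf)
  expect_equal(nm2$image_id, "bg")
  expect_equal(nm2$values, nm$values, tolerance = 1e-6)    # 32-bit storage
})
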