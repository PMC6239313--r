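# Shared helpers: in-memory images, manifests with a memory-backed loader,
# and hand-built novelty maps. All fixtures are generated in code.

const_image <- function(h, w, rgb = c(0.5, 0.5, 0.5)) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3L))
}

noise_image <- function(h, w, seed = 1, base = 0.5, sd = 0.05) {
  set.seed(seed)
  pmin(pmax(array(base + rnorm(h * w * 3, sd = sd), dim = c(h, w, 3L)), 0), 1)
}

# manifest over named in-memory arrays + loader keyed by the fake path
mem_manifest <- function(imgs) {
  tibble::tibble(
    id = names(imgs),
    path = names(imgs),
    width = vapply(imgs, function(x) dim(x)[2], integer(1)),
    height = vapply(imgs, function(x) dim(x)[1], integer(1)),
    cluster_id = NA_integer_
  )
}

mem_loader <- function(imgs) {
  function(path) imgs[[path]]
}

make_nm <- function(values, image_id = "img", dilated = TRUE,
                    patch_edge = 13L, stride = 2L) {
  structure(
    list(values = values, image_id = image_id, dilated = dilated,
         patch_edge = patch_edge, stride = stride),
    class = "novelty_map"
  )
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(patch_edge = 9L, epochs = 15L, n_train_patches = 300L,
         minibatch = 64L, seed = 42L),
    list(...))
  do.call(aen_config, args)
}

# write a small RGB png and return its path
write_tmp_png <- function(pixels, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".png")
  png::writePNG(pixels, path)
  path
}
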