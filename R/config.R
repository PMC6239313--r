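#' Pipeline configuration
#'
#' One validated record of every tunable pipeline parameter with the
#' published defaults, shared by the R functions and the command-line
#' driver. Unknown keys are rejected on load so typos fail loudly.
#'
#' @param K Number of background clusters (default 5).
#' @param patch_edge,compression,learning_rate,epochs,minibatch,n_train_patches,slice_rows
#'   Background-model settings, see [aen_config()].
#' @param stride Convolution stride for novelty maps (default 2).
#' @param percentile Threshold percentile (default 0.99).
#' @param min_box_edge Minimum proposal edge, px (default 30).
#' @param dilation_edge Dilation kernel edge; `NULL` = patch edge.
#' @param per_class_limit Review limit per class (default 600).
#' @param crop_size Training-crop edge, px (default 500).
#' @param pad_multiple Inference padding divisor (default 64).
#' @param thumb_size,n_pcs,bins,nstart Clustering-feature settings, see
#'   [cluster_images()].
#' @param review_rate,setup_cost,trad_rate Time-model parameters, see
#'   [time_model_params()].
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(K = 5L, patch_edge = 39L, compression = 0.1,
                            learning_rate = 1e-3, epochs = 100L,
                            minibatch = 128L, n_train_patches = 10000L,
                            slice_rows = 8L, stride = 2L,
                            percentile = 0.99, min_box_edge = 30L,
                            dilation_edge = NULL, per_class_limit = 600L,
                            crop_size = 500L, pad_multiple = 64L,
                            thumb_size = 32L, n_pcs = 8L, bins = 256L,
                            nstart = 10L, review_rate = 18.34,
                            setup_cost = 12327, trad_rate = 89.27,
                            seed = 1L) {
  cfg <- list(
    K = assert_count(K, "K"), patch_edge = patch_edge,
    compression = compression, learning_rate = learning_rate,
    epochs = epochs, minibatch = minibatch,
    n_train_patches = n_train_patches, slice_rows = slice_rows,
    stride = assert_count(stride, "stride"),
    percentile = percentile,
    min_box_edge = assert_count(min_box_edge, "min_box_edge"),
    dilation_edge = dilation_edge,
    per_class_limit = assert_count(per_class_limit, "per_class_limit"),
    crop_size = assert_count(crop_size, "crop_size"),
    pad_multiple = assert_count(pad_multiple, "pad_multiple"),
    thumb_size = assert_count(thumb_size, "thumb_size"),
    n_pcs = assert_count(n_pcs, "n_pcs"),
    bins = assert_count(bins, "bins"),
    nstart = assert_count(nstart, "nstart"),
    review_rate = review_rate, setup_cost = setup_cost,
    trad_rate = trad_rate,
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$percentile <= 0 || cfg$percentile >= 1) {
    abort("`percentile` must lie strictly between 0 and 1.")
  }
  # validate the autoencoder block eagerly
  invisible(as_aen_config(cfg))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
as_aen_config <- function(config) {
  aen_config(
    patch_edge = config$patch_edge, compression = config$compression,
    learning_rate = config$learning_rate, epochs = config$epochs,
    minibatch = config$minibatch,
    n_train_patches = config$n_train_patches, seed = config$seed,
    slice_rows = config$slice_rows
  )
}

#' @rdname pipeline_config
#' @export
time_model_from_config <- function(config) {
  time_model_params(review_rate = config$review_rate,
                    setup_cost = config$setup_cost,
                    trad_rate = config$trad_rate)
}

#' Read / write a pipeline configuration as YAML
#'
#' `read_pipeline_config()` overlays the file's keys on the defaults and
#' rejects unknown keys.
#'
#' @param path YAML file.
#' @return A `pipeline_config` (read) / `path` invisibly (write).
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown configuration key(s) in %s: %s", path,
                  paste(bad, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-16s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else format(x[[nm]])))
  }
  invisible(x)
}
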