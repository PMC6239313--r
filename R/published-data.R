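# Reference measurements from the published evaluation of this annotation
# workflow on three marine AUV surveys, shipped as plain CSV so the
# closed-form quantities (F2 scores, time-model rates, speed-up) can be
# recomputed rather than hard-coded.

#' Published reference measurements
#'
#' `published_validation_results()` returns the segmentation scores of the
#' trained instance-segmentation model on each survey's 50-image
#' validation subset: recall and precision in percent, plus the number of
#' training samples collected. `published_annotation_sessions()` returns
#' the logged manual-session measurements: Stage II filtering/refinement
#' durations (minutes, per 500 training images), candidate review
#' durations (minutes, per 50 validation images), tiling factors and the
#' fully manual annotation rates — the inputs of [fit_time_model()].
#'
#' @return A tibble.
#' @export
published_validation_results <- function() {
  df <- utils::read.csv(system.file("extdata", "validation_results.csv",
                                    package = "benthoscan"),
                        stringsAsFactors = FALSE)
  as_tibble(df)
}

#' @rdname published_validation_results
#' @export
published_annotation_sessions <- function() {
  df <- utils::read.csv(system.file("extdata", "annotation_sessions.csv",
                                    package = "benthoscan"),
                        stringsAsFactors = FALSE)
  as_tibble(df)
}
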