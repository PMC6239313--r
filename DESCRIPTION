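Package: benthoscan
Title: Autoencoder Novelty Detection to Bootstrap Annotation of Seabed
    Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Machine-learning-assisted annotation of large benthic photo
    surveys. Images are clustered by seabed appearance, a shallow
    autoencoder is trained per cluster as a data-driven background model,
    and reconstruction-error novelty maps are thresholded into ranked
    square training proposals for human review. The package also provides
    the review bookkeeping (filtering, circle refinement, 500x500
    training crops, augmentation) around a pluggable instance-segmentation
    backend, circle extraction from segmentation masks, region-level
    detection metrics (recall, precision, F2), a parameter-search
    harness, an annotation-time cost model, and a synthetic seabed image
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
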