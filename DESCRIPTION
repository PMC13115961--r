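Package: mirsa
Title: Spatial-Autocorrelation Tissue-Type Annotation for Mid-Infrared
    Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational tissue-type annotation for mid-infrared (MIR)
    hyperspectral microscopy of tissue sections. Selects discriminant
    wavenumbers per tissue type with a random-forest permutation-importance
    ranking and a specificity error test, fuses them into single-plane
    projection images, and maps significant clusters of high intensity
    (hotspots) with the local Moran's I statistic under conditional
    permutation inference on masked pixel grids. Supports cohort-wide
    "super image" processing, reference-based calibration of the
    significance level for new samples, pixel-level evaluation metrics
    against pathology label maps, and a seeded synthetic cohort generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    signal,
    ranger,
    png,
    tiff,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    pROC
Config/testthat/edition: 3
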