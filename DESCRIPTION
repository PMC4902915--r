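Package: tillerview
Title: Top-View Image Phenotyping of Spaced Perennial Ryegrass Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble segmentation of top-view field images of spaced
    perennial ryegrass (Lolium perenne) plants and extraction of image-based
    growth traits. Eight complementary segmentation operators (two colour
    thresholds, two texture operators, four edge operators) are fused by a
    4-of-8 majority vote into a composite plant mask. Masks are scored by
    precision, recall and their harmonic mean (F); composite areas are
    converted to base area, regrowth and first-year lateral expansion on a
    thermal-time axis and correlated with manual measurements such as tiller
    counts and leaf growth. A seeded generator of field-like synthetic scenes
    with exact ground-truth masks supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    withr,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
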