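Package: whistlemod
Title: Categorization and Species Comparison of Dolphin Whistle Contours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing species information in the frequency-modulation
    patterns of delphinid whistles. Provides an adaptive-resonance categorizer
    with dynamic-time-warping similarity for unsupervised grouping of whistle
    contours into types, a shared/species-specific/single-encounter type
    taxonomy, a rule-based detector for oscillatory frequency contours, a
    permutation test for an excess of species-specific types, ROCCA-style
    contour feature extraction, and random-forest species classification over
    whistle-type subsets. A seeded two-species repertoire simulator with known
    ground truth supports end-to-end validation without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    randomForest,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
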