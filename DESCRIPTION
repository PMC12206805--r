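Package: hyperleaf
Title: Hyperspectral Leaf Disease Identification Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for identifying leaf diseases from
    visible/near-infrared hyperspectral reflectance cubes. Covers ENVI
    cube I/O and white/dark reflectance calibration, Otsu-based leaf
    segmentation and mean-spectrum extraction, spectral preprocessing
    (standard normal variate), chemometric wavelength selection by
    competitive adaptive reweighted sampling (CARS) and the successive
    projections algorithm (SPA), classical classifiers (PLS-DA, RBF
    SVM with grid search), a family of lightweight spectral-spatial
    convolutional networks built on ShuffleNetV2 units (including a
    hybrid 3D-to-2D architecture), confusion-matrix metrics with
    Dunn/Bonferroni significance testing, and a seeded synthetic
    hyperspectral leaf simulator that provides ground truth for every
    pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    jsonlite,
    e1071,
    rlang,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    png,
    withr
Config/testthat/edition: 3
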