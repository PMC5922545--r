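Package: phenotray
Title: Automated Tray-Based Plant Phenotyping from Top-View Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An automated image-analysis pipeline for high-throughput
    top-view plant phenotyping on multi-pot trays. Provides a seeded
    synthetic tray-image generator with exact ground truth, red
    fiducial-marker detection with homography-based perspective
    rectification, grid cropping and cataloging of per-pot images,
    SLIC superpixel over-segmentation with mean CIE L*a*b* colour
    features, random-forest/SVM/multi-layer-perceptron plant-versus-
    background classifiers, morphological mask post-processing,
    per-pot growth time-series export, and a precision-recall /
    average-precision classifier evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    e1071,
    farver,
    grDevices,
    jsonlite,
    png,
    randomForest,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
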