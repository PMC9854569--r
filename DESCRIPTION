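Package: starseg
Title: Star-Convex Polygon Instance Segmentation of Adherent Cells
Version: 0.1.0
Authors@R:
    person("Maintainer", "Starseg", email = "maintainer@starseg.org", role = c("aut", "cre"))
Description: Instance segmentation of adherent, circular-like cells in
    single-channel microscopy images using star-convex polygon detection.
    Instance label maps are encoded into per-pixel object-probability and
    radial-distance regression targets, a small attention-gated
    encoder-decoder convolutional network predicts both maps, and polygon
    proposals are decoded and filtered with a polygon-based adaptive
    non-maximum suppression.  Includes the joint binary cross-entropy /
    weighted mean-absolute-error loss, pixel- and object-level evaluation
    metrics (Dice, true/false positive rates, miss rate, average
    precision), a seeded generator of synthetic adherent-cell images with
    ground truth, and a command-line interface covering data generation,
    training, prediction, evaluation and ablation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
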