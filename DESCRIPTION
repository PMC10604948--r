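Package: cephmark
Title: Cephalometric Landmark Detection with an Attention-Based Stacked
    Fully Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects 19 cephalometric landmarks on lateral cephalograms by
    Gaussian-heatmap regression with a stacked encoder-decoder network that
    combines multi-scale inputs, dual (spatial and channel) attention at the
    first bridge, multi-path dilated convolutions, and deep supervision.
    Includes the full training loop (cross-entropy loss with deep
    supervision, RMSprop, reduce-on-plateau schedule, geometric and
    intensity augmentation), mean-radial-error and successful-detection-rate
    evaluation in millimetres, the seven standard clinical measurements
    (ANB, SNB, SNA, ODI, APDI, FHI, FMA) with anatomical-type
    classification, and a seed-deterministic synthetic cephalogram phantom
    generator with exact ground-truth landmarks for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
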