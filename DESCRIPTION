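Package: rifseg
Title: RGB-Infrared Fusion Segmentation and Canopy Development Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Time-series canopy phenotyping toolchain for field crops imaged
    with co-registered RGB and infrared cameras. Implements a dual-encoder
    fusion segmentation network (ResNet-backbone encoders, Upception
    fusion/upsampling blocks, symmetric decoder) trained with a windowed
    structural-similarity plus total-variation objective alongside pixel-wise
    supervision; pixel-level precision/recall/F1 evaluation; per-leaf
    minimum-area-rectangle morphometrics with two-stage leaf-type
    classification; and penalized-spline growth-curve modelling of canopy
    cover against cumulative thermal time with extraction of five
    canopy-development traits. Ships a synthetic field-scene and growth-curve
    generator for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    mgcv,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
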