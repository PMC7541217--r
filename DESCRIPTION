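Package: cephmark
Title: Bayesian Coarse-to-Fine Cephalometric Landmark Detection with
    Confidence Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage detection of cephalometric landmarks on lateral
    skull radiographs. A low-resolution screening stage proposes a region
    of interest per landmark with a patch-classification convolutional
    network; a high-resolution stage scores every pixel of the region with
    Monte-Carlo-dropout Bayesian forward passes, combines the predictive
    mean and uncertainty through an exponential-tanh score weighting, and
    reports the score-weighted centroid together with a 95 percent
    confidence ellipse. Includes landmark-error and successful-detection-
    rate (SDR) evaluation, eight standard orthodontic skeletal parameters
    (ANB, SNA, SNB, ODI, APDI, FHI, FMA, MW) with threshold-based
    classification and confusion matrices, integer-count recovery from
    printed confusion-matrix percentages, and a synthetic cephalogram
    generator so the full pipeline can be trained and tested at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    tools,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
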