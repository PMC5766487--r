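Package: dhdecoder
Title: Decoding Hindlimb Joint Kinematics from Dorsal Horn Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for decoding continuous hip, knee and ankle
    joint-angle trajectories from extracellular spike activity recorded in the
    dorsal horn of the spinal cord. Provides a synthetic generator of
    stepping-like limb kinematics and position-tuned spiking units, band-pass
    filtering and amplitude-threshold spike detection with simplified
    PCA/k-means sorting, firing-rate and interspike-interval feature
    extraction, a two-hidden-layer recurrent multilayer perceptron trained by
    Levenberg-Marquardt, a two-level stacked-generalization ensemble fusing
    the two feature streams, and evaluation metrics (normalized RMS error,
    coefficient of determination, histogram mutual information).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
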