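Package: anomdiff
Title: Classification of Anomalous Diffusion Modes in Single-Particle
    Tracking Trajectories with Compact 1-D Residual Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-dimensional single-particle-tracking trajectories
    for four diffusion modes (normal diffusion, directed motion, confined
    diffusion and subdiffusive fractional Brownian motion) with controlled
    localization noise, computes time-averaged mean squared displacement
    (TAMSD) based trajectory features, and classifies trajectories with a
    compact one-dimensional residual convolutional network trained from
    scratch. Includes exact fractional Gaussian noise sampling via circulant
    embedding, stratified dataset assembly, a configurable XResNet-style
    architecture family with exact trainable-parameter accounting, training
    with optional selective backprop, and confusion-matrix based evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
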