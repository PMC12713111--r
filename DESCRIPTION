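Package: objspace
Title: Time-Resolved EEG Decoding and Representational Similarity
    Analysis of Object-Space Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for rapid serial visual
    presentation (RSVP) EEG experiments probing the dimensions of visual
    object space: aspect ratio (stubby versus spiky shape), animacy and
    category. Generates synthetic stimulus sets with controlled aspect
    ratio, yoked intact/silhouette experiment designs, and multi-subject
    64-channel epoch data with time-localized condition effects. Provides
    shrinkage-regularized linear discriminant decoding (whole-head
    time courses, sensor searchlight, cross-decoding across dimensions,
    temporal generalization, pairwise decoding), representational
    similarity analysis with model dissimilarity-matrix regression, and
    Jeffreys-Zellner-Siow Bayes-factor time courses with interval-null
    Cauchy priors.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
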