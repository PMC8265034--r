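Package: mrfepi
Title: Joint MRF-EPI Quantitative Mapping and White-Matter Lesion
    Probability Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and reconstruction pipeline for magnetic resonance
    fingerprinting with an echo-planar readout (MRF-EPI). Provides a seeded
    digital brain phantom with multiple-sclerosis-like white-matter lesions,
    a 35-frame magnitude fingerprint forward model with Rician noise,
    dictionary construction and voxel-wise pattern matching for T1/T2*/B1+
    mapping, Marchenko-Pastur PCA denoising, a multi-output regression U-net
    (35 baseline images in; T1, T2*, tissue- and lesion-probability maps
    out) with four loss functions and the full set of network variants, and
    evaluation metrics (dice, lesion detection rate, threshold sweeps,
    per-lesion statistics, cross-section profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
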