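Package: elscape
Title: Energy-Landscape Analysis of Binarized Brain States with Pairwise
    Maximum Entropy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits pairwise maximum entropy (Ising) models to binarized
    ROI time series, characterizes the resulting energy landscape (local
    minima, basins, basin depths), compares per-state energies between
    subject groups with Bonferroni-corrected t-tests and identifies
    complementary paired activation states, performs ROI-to-ROI
    Fisher-z connectivity contrasts with spatial pairwise clustering
    (SPC) permutation cluster-mass inference, and correlates paired-state
    probabilities with behavioral covariates. Includes a synthetic
    two-group cohort generator with planted coupling differences so the
    whole pipeline is testable without access to raw fMRI data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
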