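Package: mpiscan
Title: Sequence Analysis, Simulation and System-Matrix Reconstruction for a
    Head-Scale Magnetic Particle Imaging Scanner
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for magnetic particle imaging (MPI) with a Lissajous-type
    field-free-point trajectory and a slow triangular selection-field sweep:
    exact sequence and frequency-index algebra, ideal and spherical-harmonic
    magnetic field models, a Langevin nanoparticle signal simulator with
    robot-style system-matrix calibration emulation, SNR-based frequency
    selection and regularized Kaczmarz image reconstruction (L2/L1,
    nonnegativity, multi-patch and single-patch processing, multi-contrast
    stacking, over-gridding), bolus perfusion parameter maps (TTP, MTT, rCBF,
    rCBV), and scanner characterization protocols (spatial resolution and
    detection-limit studies) exercised entirely on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
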