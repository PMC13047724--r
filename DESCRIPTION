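Package: sersflow
Title: Event Detection and Peptide Classification for Flow-Through
    Single-Molecule SERS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of time-resolved single-photon spectral
    streams from flow-through surface-enhanced Raman spectroscopy (SERS)
    experiments, in which peptides translocate one by one through plasmonic
    nanopores and a SPAD camera records photon-count spectra at 100
    microsecond resolution. Provides a calibrated synthetic stream generator
    (Poisson background with slow drift, Dirichlet-perturbed peptide
    fingerprints, faulty detector channels), preprocessing (bad-pixel removal,
    adaptive Wiener smoothing), translocation-event detection by segmented
    median baseline subtraction and robust thresholding, single-event spectrum
    extraction and photon statistics, a supervised discrimination protocol
    (Yeo-Johnson power transform, PCA, random forest, repeated stratified
    70/30 evaluation), N-event averaging accuracy curves with an exact
    majority-vote oracle, and classifier-based mixture-composition estimation
    with a hypergeometric reference model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    caret,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
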