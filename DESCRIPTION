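Package: neostress
Title: Bradycardia-Based Stress Classification for Neonatal Multichannel
    Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects bradycardia plus oxygen-desaturation (hypoxic) events in
    multichannel neonatal recordings (EEG, RR tachogram, SpO2), extracts
    univariate heart-rate-variability, oximetry and EEG features (temporal and
    wavelet spectral statistics, Poincare descriptors, phase-rectified signal
    averaging slopes, wavelet-leader multifractal log-cumulants) together with
    network-physiology features built from surrogate-validated imaginary
    wavelet coherence graphs, and classifies events as belonging to stressed
    versus non-stressed patients with a subspace linear-discriminant ensemble
    under leave-one-patient-out evaluation.  A synthetic-cohort generator with
    controllable stress effect sizes makes every stage testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    zoo,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
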