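Package: specFusion
Title: Dual-Modality NIR/SERS Spectral Fusion Calibration with HSIC-Based
    Wavelength Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate calibration toolkit for quantifying pesticide
    residues from paired near-infrared (NIR) and surface-enhanced Raman
    (SERS) spectra. Implements spectral preprocessing (AirPLS baseline
    correction, multiplicative scatter correction, standard normal variate,
    Savitzky-Golay smoothing, min-max scaling), NIPALS partial least squares
    regression with k-fold cross-validation, an iterative wavelength selector
    driven by the Hilbert-Schmidt Independence Criterion with weighted binary
    matrix sampling (HSIC-VSIO), direct and feature-level data fusion, the
    RMSE/R-squared/RPD evaluation protocol, prominence-ranked peak detection,
    and a synthetic dual-modality spectrum generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    jsonlite,
    xml2,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
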