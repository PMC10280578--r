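Package: hyperseed
Title: Hyperspectral Seed Spectra Processing and Random-Subspace Ensemble
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for variety identification of crop seeds from
    visible/near-infrared hyperspectral images. Covers reflectance
    calibration of hyperspectral cubes against white and dark reference
    frames, threshold-based seed segmentation and per-seed mean-spectrum
    extraction, row-wise spectral pretreatments (multiplicative scatter
    correction, standard normal variate, Savitzky-Golay first derivative),
    Kennard-Stone sample partitioning, wavelength selection by competitive
    adaptive reweighted sampling (CARS) and iteratively retaining
    informative variables (IRIV) over a compiled SIMPLS partial
    least-squares core, and a random-subspace ensemble classifier with
    weighted-average score combination. Includes a calibrated synthetic
    spectra generator so the full pipeline is testable without instrument
    data, and evaluation via confusion matrices, overall precision and
    Cohen's kappa.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    e1071,
    jsonlite,
    rpart,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
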