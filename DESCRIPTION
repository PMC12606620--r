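Package: etalonsim
Title: Physics-Based Simulation and Neural Correction of CCD Etaloning in Raman Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward-models the interference fringes (etaloning) that
    back-illuminated CCD detectors imprint on Raman spectra, and inverts them
    with a one-dimensional convolutional encoder-decoder network trained by
    two-phase transfer learning.  A coherent transfer-matrix solver computes
    reflectance, transmittance and absorbance of arbitrary planar multilayer
    stacks with complex refractive indices; a library of CCD layer designs
    spans interpolation (silicon-thickness variants) and extrapolation (novel
    high-index materials) scenarios; a synthetic Raman generator produces
    Lorentzian-broadened spectra with noise, shifts and silent regions; and a
    corruption module injects fluorescence baselines, quantum-efficiency
    envelopes and fringes.  The network, its optimizers and a tree-structured
    Parzen-estimator hyperparameter search are implemented in base R; model
    quality is scored with spectral-angle, RMSE, MAE and normalized Euclidean
    metrics under leave-one-design-out cross-validation, with a
    Savitzky-Golay smoothing baseline for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
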