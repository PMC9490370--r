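Package: eemcal
Title: Chemometric Calibration for Excitation-Emission Matrix Fluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of strongly overlapping fluorophores from
    excitation-emission matrix (EEM) fluorescence landscapes. Provides
    Rayleigh/Raman scatter excision with interpolation infilling, contour
    vector extraction, and three calibration engines: lasso regression on
    contour values, interval partial least squares (iPLS) with joint
    interval/component selection by cross-validated RMSECV, and trilinear
    N-PLS (tri-PLS1) on the full three-way cube with latent-variable
    selection by PRESS. Includes a synthetic EEM generator with trilinear
    two-fluorophore signals, scatter ridges and noise, spike-recovery
    validation statistics (Rc, Rp, RMSEC, RMSEP, recovery), and a
    config-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    glmnet,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
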