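Package: serscal
Title: Chemometric Calibration of Surface-Enhanced Raman Spectra for Blood
    Hormone Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying growth hormone and testosterone in blood
    from surface-enhanced Raman (SERS) spectra. Provides a synthetic
    blood-SERS spectrum generator with concentration-sensitive Lorentzian
    bands and a saturating adsorption response, spectral preprocessing
    (vector/max/area normalization, group averaging, band-intensity
    statistics with one-way ANOVA), principal-component score extraction,
    multilayer-perceptron calibration models trained with resilient
    backpropagation with weight backtracking (Rprop+), validation metrics
    (RMSE, coefficient of determination), multivariate detection and
    quantification limits from blank leverages, Bateman pharmacokinetic
    time-course simulation and prediction, and ELISA standard-curve
    (Boltzmann / exponential-decay) fitting and inverse prediction for
    reference-method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
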