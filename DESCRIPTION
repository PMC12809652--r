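Package: serdsuq
Title: Calibrated Uncertainty Quantification for SERDS Spectral Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and calibrated uncertainty
    quantification for regression on shifted-excitation Raman difference
    spectroscopy (SERDS) data, with soil organic carbon (SOC) estimation as
    the reference task. Provides a seeded synthetic dual-laser SERDS
    generator, the standard chemometric signal chain (multiplicative
    scatter correction, common-mode rejection, SERDS differencing,
    Savitzky-Golay smoothing, uniform resampling), a compact 1D
    convolutional network with five interchangeable uncertainty heads
    (heteroscedastic Gaussian, quantile regression, Monte Carlo dropout,
    Bayes by backprop, deep ensembles), split-conformal calibration of any
    of them, and an evaluation suite covering coverage curves, calibration
    RMSE, sharpness, consistency and informativeness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
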