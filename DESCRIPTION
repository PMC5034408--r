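Package: prosthermal
Title: Thermal Time Constants and Gaussian-Process Skin Temperature
    Prediction for Lower-Limb Prostheses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for modelling heat transfer through prosthetic liner and
    socket materials and for non-invasively predicting residual-limb skin
    temperature. Implements first-order (lumped-capacitance) thermal response
    simulation of single and stacked prosthetic layers, estimation of thermal
    time constants from temperature-time logs by the logarithmic method
    (log-linear regression on the decaying difference from steady state), a
    bundled library of measured time constants for common liner and socket
    materials, and Gaussian-process regression with a squared-exponential
    covariance whose length scale is fixed to the prosthesis stack's thermal
    time constant, yielding skin-temperature predictions with 95% intervals.
    A synthetic trial generator emulates rest/walk/rest amputee recordings
    for testing and calibration studies.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
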