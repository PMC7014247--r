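Package: etongue
Title: Cross-Interference Calibration for Two-Channel Taste Sensor Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibration and mixture deconvolution for potentiometric
    electronic-tongue measurements in which a sweetness sensor and a
    saltiness sensor cross-respond to each other's analytes. Implements a
    Weber-Fechner logarithmic forward response model for the two sensors'
    relative values, its analytic two-by-two inversion, and an
    interaction-corrected inverse model that predicts acesulfame K and
    NaCl concentrations simultaneously from the paired sensor readings.
    Includes trust-region nonlinear least-squares fitting of the model
    constants to factorial calibration designs, a seedable synthetic
    panel simulator, predicted-versus-actual evaluation reports, tidy CSV
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    tibble,
    dplyr,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    yaml,
    optparse
Config/testthat/edition: 3
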