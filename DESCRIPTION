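Package: viscofit
Title: Viscoelastic Model Identification for Soft Gel Compression Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and system identification of nonlinear
    two-Maxwell-body viscoelastic models for soft biomaterial scaffolds
    (collagen gels) under unconfined uniaxial compression. Implements a
    Mooney-Rivlin-inspired nonlinear spring model, its Neo-Hookean special
    case, a Hammerstein (cubic static block + linear two-Maxwell dynamics)
    model and the plain linear two-Maxwell transfer function; estimates
    their parameters from sampled strain/load records by continuous-time
    instrumental-variable (SRIVC-style) identification and grey-box
    Levenberg-Marquardt prediction-error minimisation; and provides the
    FIT/FPE validation metrics, Mooney-Rivlin linearisation and hysteresis
    diagnostics, synthetic mechanical-test protocol generators (ramp,
    triangular cycling, step relaxation) and end-to-end identification/
    validation workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    Matrix
Suggests:
    deSolve,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
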