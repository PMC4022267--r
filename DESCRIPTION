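Package: bootgof
Title: Parametric Bootstrap Model Rejection with Combined Goodness-of-Fit
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Parametric-bootstrap goodness-of-fit testing for predictor-based
    models of noisy data, as used in systems biology model rejection. Provides
    bootstrapped chi-square and Durbin-Watson tests, their (unsound) simplistic
    p-value combinations, a two-dimensional joint-density test based on
    kernel-density highest-density regions (chi-square vs Durbin-Watson, or
    chi-square vs chi-square with a second "help" model), and a bootstrapped
    log-likelihood-ratio test for non-nested models. Includes built-in static
    (linear, exponential) and dynamic (mass action, Michaelis-Menten) test-case
    models, a pluggable predictor interface, weighted least-squares and bounded
    multi-start parameter estimation, and an evaluation harness producing ROC
    curves, partial AUC, and type-I-error calibration at configurable scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    deSolve,
    yaml
Config/testthat/edition: 3
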