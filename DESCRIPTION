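Package: platekin
Title: Steady-State Platelet Survival-Curve Models with Competing Senescent
    and Random Loss
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models and fits steady-state cell-population survival curves
    under two competing fates: age-dependent senescent death with a
    distributed natural lifespan, and age-independent random loss at a
    constant rate. Implements the lognormal-senescent (LS), Dornhorst, and
    hybrid Dornhorst-lognormal-senescent (DLS) models, prediction of
    double-label "cohort" survival curves via an age-structured transport
    equation, multi-start bounded least-squares fitting of in-vivo pulse
    label data, Monte Carlo confidence intervals by refitting simulated
    data, nested-model F-tests, an individual-based stochastic simulator
    for validation, and simulation studies of how experimental noise limits
    constraint of the random loss fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
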