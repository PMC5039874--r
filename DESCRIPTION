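Package: anginacua
Title: Markov Cohort Cost-Utility Model for Chronic Stable Angina
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-utility model comparing trimetazidine as
    add-on therapy to standard of care against standard of care alone in
    chronic stable angina, from a third-party payer perspective. Implements a
    five-state Markov cohort model over four 3-month cycles with
    state-dependent mortality, per-category cost and QALY accounting,
    incremental cost-effectiveness analysis, one-way (tornado) sensitivity
    analysis, drug price rebate scenarios, and probabilistic sensitivity
    analysis with gamma/beta/Dirichlet parameter uncertainty and
    cost-effectiveness acceptability curves. Ships the Greek evaluation's
    parameter set as a built-in fixture, a structured-text (JSON)
    configuration format, a synthetic parameter generator for property-based
    testing, and an individual-level microsimulation oracle for validating
    the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
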