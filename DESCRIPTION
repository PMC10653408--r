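Package: retscreen
Title: Markov Cohort Cost-Effectiveness Analysis of Diabetic Retinopathy
    Screening Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic modelling of diabetic retinopathy (DR)
    screening in a rural diabetic population. Implements a seven-state
    Markov cohort model of the natural history of DR (no DR through
    non-proliferative and proliferative stages to blindness and death),
    three screening strategies (no screening, artificial-intelligence-based
    grading, ophthalmologist grading) with laser-treatment effects and
    itemized programme costing, discounted half-cycle-corrected cost and
    QALY accrual, incremental cost-effectiveness and dominance analysis,
    one-way (tornado) and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and a synthetic paired
    screening-cohort generator with diagnostic agreement statistics
    (Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
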