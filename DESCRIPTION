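Package: mamsrb
Title: Multi-Arm Multi-Stage Clinical Trial Designs with a Risk-Benefit
    Selection Rule
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design and simulation of multi-arm multi-stage (MAMS) clinical
    trials in which several experimental arms are compared with a shared
    control on a bivariate normal (efficacy, safety) endpoint. At the first
    analysis the arm with the best weighted risk-benefit trade-off among those
    meeting a minimum safety requirement is selected; stopping boundaries for
    the selected arm's efficacy and safety score statistics are calibrated by
    numerical integration of limiting post-selection distributions so that the
    familywise error rate is strongly controlled, and sample size is found by
    a one-dimensional information search attaining a target disjunctive power.
    Multi-stage extensions use alpha-spending boundary schedules with binding
    futility. A seeded Monte-Carlo trial simulator doubles as an independent
    oracle for every numerically integrated quantity and drives an
    operating-characteristics engine (error-rate grids, mixed null
    configurations, correlation misspecification sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
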