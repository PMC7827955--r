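Package: chemofit
Title: Time-Independent Estimation of Chemotherapy Efficacy from Cell
    Growth Curves
Version: 0.1.0
Authors@R:
    person("chemofit", "maintainers", email = "chemofit@example.org",
           role = c("aut", "cre"))
Description: Models in vitro cancer-cell growth under chemotherapy as
    logistic growth whose rate is scaled by (1 - efficacy), with efficacy
    given by an Emax pharmacodynamic model. Provides a two-step fitting
    procedure (control fit for growth rate and carrying capacity, then a
    joint treated fit for Emax and IC50) by Nelder-Mead minimisation of
    the sum of squared residuals, bootstrap percentile confidence
    intervals, forward simulation of MTT viability assays, extraction of
    the measurement-day-dependent apparent IC50, and synthetic-data
    generators that emulate replicated cell-count and viability designs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
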