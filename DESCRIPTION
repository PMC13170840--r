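Package: mepoCEA
Title: Markov Cohort Cost-Effectiveness Model for Mepolizumab in Severe
    Eosinophilic Asthma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lifetime-horizon Markov cohort model evaluating mepolizumab
    plus standard of care against placebo plus standard of care in severe
    eosinophilic asthma from a societal perspective.  Implements a 2-week
    cycle model with exacerbation tunnel states, state-specific asthma
    mortality, half-cycle correction and annual discounting; direct medical,
    adverse-event and human-capital indirect costing; and base-case,
    subgroup, deterministic (tornado) and probabilistic (Monte Carlo with
    cost-effectiveness acceptability curves) analyses.  Ships a synthetic
    parameter fixture and random-parameter generators so every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
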