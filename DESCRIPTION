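Package: lncPairSig
Title: Prognostic Signatures from Rank-Based Immune lncRNA Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates prognostic signatures from the relative
    expression ordering of immune-related long noncoding RNA (lncRNA) pairs
    in tumour cohorts. Implements immune coexpression and differential
    expression screening, binary pair encoding with a constancy filter,
    Lasso-Cox and stepwise Cox signature construction, time-dependent ROC
    with AIC-based risk dichotomization, Kaplan-Meier validation,
    immune-infiltration and drug-sensitivity association statistics, and
    Monti consensus subtyping, together with a fully labelled synthetic
    cohort generator for end-to-end validation against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
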