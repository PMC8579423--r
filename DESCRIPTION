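Package: dormantlink
Title: Reactivating Dormant Randomised Trials by Probabilistic Linkage to
    Administrative School Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for following up dormant randomised controlled trials by
    linking retained participant identifiers to an administrative pupil
    register and re-estimating intervention effects on academic outcomes.
    Implements identifier standardisation, blocked candidate generation with
    Fellegi-Sunter agreement weighting and constrained one-to-one link
    selection, derivation of standardised exam-score and binary attainment
    outcomes, intention-to-treat estimation with chained multiple imputation,
    heteroscedasticity-robust (sandwich) variance, Rubin pooling, a
    sensitivity-analysis matrix, and a minimum-detectable-effect calculator.
    A synthetic-data module generates a pupil register and seven infant
    formula trial cohorts with ground-truth links so the whole pipeline is
    testable without access to confidential data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
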