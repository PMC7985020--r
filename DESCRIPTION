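Package: famprs
Title: Polygenic Risk Score Analysis for Multiplex Family Cohorts
Version: 0.1.0
Authors@R: person("famprs", "developers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for polygenic risk score (PRS) analyses in family-based
    designs: harmonisation and filtering of GWAS summary statistics,
    threshold-based PRS construction with relative risk-load scaling,
    shared-disorder PRS via random-effects meta-analysis, disorder-specific
    summary statistics through an LD-score-regression based conditional
    correction, kinship-aware logistic and linear mixed models with
    bootstrap and permutation inference, an exact-binomial simulated-PRS
    null calibration, and a liability-threshold pedigree simulator for
    end-to-end testing without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
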