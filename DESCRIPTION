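Package: cxcl13index
Title: CXCL13 Index Stratification and Outcome Analysis for CIS/RIS Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes intrathecal CXCL13 production indices (the CXCL13
    index: the CSF/serum CXCL13 ratio normalised by the albumin quotient),
    stratifies clinically or radiologically isolated syndrome (CIS/RIS)
    patients into high, low and indeterminate groups under a dual threshold
    system with a CSF-only fallback rule, and evaluates the stratification
    against multiple sclerosis activity outcomes via exact contingency
    tests, diagnostic performance with Clopper-Pearson intervals, and
    cohort summary tables. Includes a seeded synthetic-cohort generator
    with log-normal biomarker distributions and Bernoulli and Poisson
    outcomes so the full pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
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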