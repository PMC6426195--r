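Package: obcost
Title: Incidence-Based Cost-of-Illness Analysis of Obstetric Complications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for incidence-based cost-of-illness analysis of obstetric
    complications at the hospital level: reciprocal (simultaneous-equation)
    cost-center allocation with capital annualization for service unit costs,
    bottom-up (micro-costing) patient treatment costs with cohort summaries,
    and a log-linear treatment-cost regression with SPSS-style stepwise
    selection, residual diagnostics, studentized-deleted-residual outlier
    trimming, and Duan smearing retransformation for predicted costs on the
    money scale. Includes a synthetic cohort, utilization and hospital-ledger
    generator so the full pipeline runs and is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, lmtest, car, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
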