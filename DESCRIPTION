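Package: vteclaims
Title: Claims-Based Identification and Incidence Estimation of Venous
    Thromboembolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for estimating the incidence, recurrence and mortality
    of venous thromboembolism (deep vein thrombosis and pulmonary embolism)
    from health-insurance claims data in which community care carries no
    diagnosis codes. Implements ICD-10 capture of hospital events, a
    three-criterion temporal algorithm identifying community-treated deep
    vein thrombosis from echo-Doppler and anticoagulant reimbursements,
    index-event adjudication with clot-migration and setting-reclassification
    rules, annual incidence per 100 000 with national extrapolation,
    twelve-month recurrence and all-cause mortality statistics
    (Kaplan-Meier cumulative incidence, chi-square and Fisher exact tests),
    and two-step univariate-screen regression models (Cox for recurrence,
    logistic for hospitalisation). Ships a calibrated synthetic claims
    generator with a retained truth log so the whole pipeline is testable
    without access to restricted claims databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    survival,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
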