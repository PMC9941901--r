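Package: portalits
Title: Propensity-Matched Interrupted Time-Series Evaluation of Patient
    Portal Effects on Primary Care Encounters
Version: 0.1.0
Authors@R:
    person("Portal", "ITS Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating the effect of patient-portal registration
    on the use of traditional primary-care services with an open-cohort,
    propensity-score-matched interrupted time-series (ITS) design.  The
    package bundles a synthetic electronic-medical-record (EMR) generator
    with known ground truth, cohort eligibility and open-cohort index-date
    assignment, index-date covariate construction, caliper-constrained
    greedy unique-first one-to-one matching with balance diagnostics,
    segmented person-year ITS regression with cluster-robust standard
    errors, and descriptive reporting including a clinician
    messaging-workload estimate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    lubridate,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
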