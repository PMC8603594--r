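Package: mdiscreen
Title: Multidrug-Interaction Screening of Patient Medication Lists
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects multidrug interactions (MDIs) on patient medication
    lists by network analysis. A per-patient interaction graph is built
    from a drug-drug interaction (DDI) knowledge base restricted to the
    contraindicated, generally-avoid and monitor-closely severity tiers;
    connected components of three or more drugs are reported as MDIs and
    classified by the mechanism through which they may amplify adverse
    drug event (ADE) risk (pharmacodynamic, pharmacokinetic, conditional).
    Includes cohort cleaning rules for outpatient medication-list
    extracts, cohort-level prevalence and severity statistics, exposure
    extrapolation onto external prescription-beneficiary counts, and a
    calibrated synthetic cohort generator for end-to-end testing without
    protected health data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
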