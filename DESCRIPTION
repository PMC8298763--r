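Package: apdclaims
Title: Medication-Based Identification of Advanced Parkinson's Disease in
    Administrative Claims
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies advanced Parkinson's disease (APD) from pharmacy
    claims by reconstructing per-patient per-day medication exposure from
    dispensing events, converting it to levodopa equivalent dose (LED), and
    flagging patients with any 30-day average dose above a threshold
    (primary rule: LED > 1000 mg/day, plus three sensitivity rules).
    Includes the claims-based validation pipeline around the classifier:
    cohort inclusion criteria with an attrition funnel, nine configurable
    claims-based severity indicators, descriptive group comparisons, and
    covariate-adjusted logistic regressions reporting odds ratios with Wald
    95% confidence intervals. A synthetic claims-cohort generator with known
    ground truth makes every stage testable without access to real Medicare
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
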