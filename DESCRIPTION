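Package: pomstat
Title: Misclassification Probability of Surface-Water Chemical Status from
    Censored Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the chemical status of surface-water bodies
    from left-censored concentration monitoring series and for quantifying the
    probability of misclassification (P_om) of that assessment. Implements the
    half-LOQ substitution rule for annual means, a modified standard deviation
    for series containing values below the limit of quantification, per-indicator
    classification against annual-average (AA-EQS) and maximum-allowable
    (MAC-EQS) quality standards including the pesticide sum rule, Student-t and
    Gumbel exceedance probabilities for the mean and maximum criteria, and a
    four-level hierarchical aggregation to a single status-level P_om per water
    body under the one-out-all-out rule. Includes a seeded synthetic monitoring
    data generator and a calibration harness.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
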