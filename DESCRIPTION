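Package: tumorresponse
Title: Tumor Growth Response Endpoints for Preclinical Radio-Immunotherapy Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw preclinical measurements (caliper tumor volumes,
    ex vivo lymph-node bioluminescence, flow-cytometry and cytokine
    summaries) into the standard endpoints of murine radio-immunotherapy
    efficacy studies: modified RECIST (mRECIST) best-response and
    best-average-response scoring with waterfall summaries, time-to-volume
    Kaplan-Meier survival with Mantel-Cox logrank comparison, growth
    area-under-curve with last-value carry-forward, draining-lymph-node
    metastasis positivity from background-corrected radiance fold changes,
    the field's metric-normalization rules, and a normality-gated
    statistical dispatcher (Shapiro-Wilk gate, Grubbs outlier screen,
    Holm-Sidak and Dunn corrections, Fisher's exact test). A cohort
    simulator with responder-class mixtures makes every stage testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
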