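Package: psymon
Title: Digital Phenotyping Analysis of Wearable and Patient-Reported Data in Schizophrenia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for continuous wearable-device
    and patient-reported outcome data collected alongside clinical visits in
    schizophrenia monitoring studies. Provides a synthetic cohort generator
    with controllable between-patient variance, cross-channel correlation,
    circular clock-time channels, device non-wear and injectable pre-relapse
    deviations; long-format metric ingestion with schema validation,
    wear-time compliance and data-coverage summaries and the PANSS-based
    relapse flag; biweekly window feature extraction with circular
    statistics; repeated-measures association analysis and intraclass
    correlation via linear mixed models; elastic-net prediction of clinical
    scales under patient-level repeated cross-validation; and an
    individualized statistical-process-control monitor that raises point
    outlier, mean-shift, variance-shift and slope-trend alerts on streaming
    daily metrics.
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
    glmnet,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
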