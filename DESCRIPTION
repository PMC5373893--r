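Package: plaqomics
Title: Multi-Omics Biomarker Discovery and Risk Prediction for
    Atherosclerotic Plaque Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for extracellular-matrix proteomics of
    atherosclerotic plaques and downstream epidemiological validation of
    candidate biomarkers. Implements spectral-count differential expression
    with NSAF normalization and a power-law global error model, empirical
    zero-count imputation scored by Shapiro-Wilk normality, moderated-t
    transcriptomic contrasts, paired secretome testing, Pearson coexpression
    networks with q-value edge thresholding, cross-omics candidate
    integration, person-based carotid ultrasound progression classification,
    and incremental risk-prediction metrics (C-statistic and Harrell's
    C-index with jackknife standard errors, DeLong comparison, categorical
    and continuous net reclassification improvement, integrated
    discrimination improvement), including Prentice-weighted case-cohort Cox
    models. A seed-controlled synthetic-data module generates every input
    type with the statistical structure the methods assume.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
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
    withr,
    limma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
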