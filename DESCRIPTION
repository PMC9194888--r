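Package: tfab
Title: Normative Standardization and Clinical Usability of a Telephone-Based
    Frontal Assessment Battery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for regression-based normative standardization of the
    telephone-based Frontal Assessment Battery (t-FAB) and similar short
    cognitive screening scores. Implements demographic adjustment of raw
    scores with the published correction equations, Equivalent Score (ES)
    classification on non-parametric tolerance limits, derivation of new
    norms from a cohort (stepwise transform selection, exact binomial
    tolerance-limit ranks, ES thresholds), psychometric validation
    (distribution-aware correlations with Bonferroni control, intraclass
    correlations, principal-component structure, paired-samples TOST
    equivalence), ROC discrimination of clinical groups with DeLong or
    Hanley-McNeil standard errors, the study design sample-size calculators
    (paired TOST, multiple regression via the noncentral F, Obuchowski ROC),
    and seeded synthetic cohort generators emulating the normative and
    clinical samples.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
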