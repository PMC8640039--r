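Package: sbmie
Title: Diet-Corrected Gut-Content Metabolomics for Soybean-Meal-Induced Enteritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for untargeted metabolomics of fish gut contents under
    soybean-meal substitution diets: per-feature differential analysis
    (fold change, Welch/Student/Wilcoxon tests, NIPALS PLS-DA variable
    importance in projection), diet-background filtration of content
    metabolomes, VIP-ranked biomarker screening with cross-ion-mode
    deduplication and cross-dose core-biomarker intersection, validation by
    z-scores, ROC/AUC and significance-masked correlation, inverse-correlation
    content/tissue metabolite-exchange classification, hypergeometric pathway
    over-representation, alpha-diversity estimators for OTU tables, and a
    seeded synthetic-data generator with planted ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
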