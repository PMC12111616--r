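Package: metabnet
Title: Untargeted Plasma Metabolomics Analysis for Autoimmune Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for case-control untargeted
    metabolomics studies of autoimmune disease (rheumatoid arthritis and
    systemic lupus erythematosus versus healthy controls). Covers pooled-QC
    random-forest drift normalization (SERRF-style), presence and QC
    reproducibility filtering, OPLS-DA/VIP with Wilcoxon-FDR feature
    selection, chemical-similarity clustering of metabolites with weighted
    module summarization, metabolite-cytokine and metabolite-HDL Spearman
    correlation networks with shortest-path embedding, combined-metabolite
    logistic biomarker scoring with ROC curves, and clinical-table group
    statistics (Kruskal-Wallis, Dunn, Freeman-Halton Fisher). Includes a
    synthetic cohort generator that emulates the study design so every
    stage is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    ranger,
    cluster,
    ChemmineR,
    ChemmineOB,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
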