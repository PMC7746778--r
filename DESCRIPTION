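Package: metabopredict
Title: Microbiome-Based Metabolite Prediction and Benchmarking
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts community metabolite profiles from microbial function
    abundance tables (KEGG orthologs or reactions) by three complementary
    strategies: a relationship-table lookup linking functions to compounds
    through reactions, enzyme-number fallback routes and transporter
    annotations; signed community-metabolic-potential scoring of
    stoichiometry-weighted gene abundances; and per-metabolite elastic-net
    regression trained on paired microbiome-metabolome cohorts with
    leave-one-study-out validation. Ships the complete head-to-head
    evaluation framework (occurrence and differential precision/recall/F1,
    Procrustes comparison of abundance matrices, permutation nulls by random
    compound draws and label shuffling) together with a ground-truth-aware
    synthetic paired-cohort generator so every stage is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
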