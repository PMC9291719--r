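Package: fsrecur
Title: Feature-Set Recurrence Analysis for Biologically Grouped SNP Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for machine-learning association analysis of genotype
    cohorts using biologically grouped SNP feature sets. Builds feature sets
    from druggable-gene/connected-gene pairs (promoter-extended gene bodies,
    enhancer links, functionality-score filters, LD pruning), runs a reduced
    template-constrained evolutionary pipeline search with feature-set
    selection over balanced case/control down-samplings, measures the
    recurrence with which the same feature set is selected across runs and
    tests it against a phenotype-permutation null, and dissects case
    heterogeneity with exact kernel SHAP attributions, Dunn-index guided
    k-means clustering and per-cluster feature rankings. Includes a synthetic
    GWAS cohort generator (LD blocks, population structure, heterogeneous
    case subgroups) so the full procedure is testable without
    access-controlled biobank data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    MASS,
    glmnet,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
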