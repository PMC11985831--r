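Package: pyropattern
Title: Pyroptosis Expression Patterns in Acute Myeloid Leukemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and validation of pyroptosis-related expression
    patterns in acute myeloid leukemia (AML) transcriptomes. Provides
    consensus non-negative matrix factorization (NMF) subtyping on a
    40-gene pyroptosis panel with silhouette-based model selection, a
    rank-pair (gene i > gene j) random-forest classifier that transfers
    across expression platforms, pseudobulk aggregation of malignant
    single-cell counts with CPM normalization, single-sample gene-set
    enrichment scoring with moderated-t differential analysis, survival
    statistics (Cox regression, Kaplan-Meier/log-rank, LASSO-Cox gene-set
    selection, parallel-analysis factor extraction), degree-based hub-gene
    ranking in protein-protein interaction clusters, and a synthetic-data
    generator that emulates the two-subtype cohort structure so the whole
    pipeline runs and is tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    mclust,
    cluster,
    pROC
Config/testthat/edition: 3
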