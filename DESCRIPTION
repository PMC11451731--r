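Package: metaprog
Title: Metaprogram Discovery and Validation for Single-Cell Tumor Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers recurrent tumor gene-expression metaprograms from
    single-cell RNA-seq count matrices by per-cohort non-negative matrix
    factorization with loading z-score and co-expression-graph gene
    prioritization, rank-based AUC (AUCell-style) activity scoring, factor
    clustering with silhouette model selection, and repeated-run stability
    selection by cross-validated classifier auROC. Downstream stages cluster
    malignant cells by metaprogram activity on a Mahalanobis k-nearest-neighbor
    graph with consensus Louvain, test cross-cohort metaprogram correspondence
    by tumor-wise Spearman correlation and a one-sided Wilcoxon test against a
    correlation floor, and associate pseudobulk signature scores with
    progression-free survival by median split and log-rank test. Includes a
    synthetic-cohort generator with planted programs and survival links for
    ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    graphics,
    igraph,
    glmnet,
    survival,
    cluster,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    uwot,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
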