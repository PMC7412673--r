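Package: scHippo
Title: Zero-Inflation Testing and Heterogeneity-Driven Hierarchical
    Clustering for Single-Cell UMI Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tests each gene of a UMI count matrix for zero inflation
    relative to a homogeneous Poisson model, interprets inflated genes as
    evidence of cell-type heterogeneity, and resolves that heterogeneity
    by iterative rounds of feature selection and PCA + K-means binary
    splits with variability-guided cluster choice. Also provides per-gene
    Poisson, negative binomial and zero-inflated negative binomial
    likelihood fits with nested likelihood-ratio diagnostics, Poisson
    two-group differential expression tests, a finite-Poisson-mixture
    count simulator, and readers/writers for 10x-style MatrixMarket and
    dense count files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
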