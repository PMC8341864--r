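Package: sccaCC
Title: Multi-Omics Subtyping and Classification by Sparse Canonical
    Correlation Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Fuses two omics views of the same samples (for example mRNA
    and miRNA expression) by projecting both onto a shared
    low-dimensional space with sparse canonical correlation analysis
    computed by L1-penalized matrix decomposition, discovers molecular
    subtypes by resampling-based consensus k-means clustering of the
    fused representation, and trains subtype classifiers that can label
    fused multi-omics samples as well as samples for which only a single
    omics view is available.  Includes cluster-significance testing,
    cross-taxonomy association tests, survival association, canonical
    variate interpretation utilities, and a seeded two-view cohort
    simulator with planted sparse canonical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    class,
    cluster,
    e1071,
    graphics,
    grDevices,
    jsonlite,
    mclust,
    randomForest,
    Rcpp,
    stats,
    survival,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
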