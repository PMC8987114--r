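Package: dccnet
Title: Weighted Co-Expression Networks and Differential Correlation
    Analysis for Case-Control Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs weighted gene co-expression networks from a
    gene-by-sample expression matrix (Pearson correlation, soft-thresholded
    adjacency with scale-free power selection, topological overlap, module
    detection on TOM dissimilarity, module eigengenes and module-trait
    association) and screens gene pairs within trait-associated modules for
    differential correlation between two conditions using Fisher's z-test
    with empirical-Bayes local false discovery rate control. Sign-switching
    gene pairs (positively correlated in one condition, negatively in the
    other) are flagged and hub genes ranked by their degree in the switched-
    pair network. Downstream helpers cover two-sample differential
    expression with Benjamini-Hochberg adjustment, hypergeometric gene-set
    enrichment against user GMT files, and Cytoscape-compatible network
    export. A synthetic two-condition expression generator with planted
    modules, trait-linked modules and planted correlation switches supports
    validation of the whole pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    mclust,
    splines,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
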