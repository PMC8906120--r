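Package: lrnet
Title: Ligand-Receptor Signaling Networks from Clustered Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes, filters, ranks and compares cell-cell ligand-receptor
    signaling networks ("connectomes") from clustered single-cell RNA-seq
    expression matrices. Builds a directed multigraph of
    celltype-ligand-receptor-celltype edges carrying two complementary
    edgeweights (a raw-connectivity product of normalized cluster means, and
    a specificity score from system-wide gene z-scores), gates edges on
    expression fraction and one-vs-rest Wilcoxon rank-sum significance,
    quantifies sending/receiving roles per signaling family via Kleinberg
    hub/authority centrality and cumulative edgeweight fractions, compares
    two conditions edge-for-edge with log fold changes and a perturbation
    score, embeds celltype-celltype vectors by mechanism-profile similarity,
    and ships a negative-binomial synthetic-data generator with planted
    ligand-receptor signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
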