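Package: netshiftr
Title: Network-Shift Biomarker Analysis for Longitudinal Microbiome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for network-based differential-abundance
    analysis of longitudinal two-arm microbiome count data: count-table
    filtering and rarefaction, alpha/beta diversity with PERMANOVA, SparCC
    compositional correlation networks per condition, inverse-variance
    integration of per-timepoint networks, topological-overlap module
    detection with connection-strength and module-importance node
    statistics, a NetMoss-style module-shift driving-force score with
    permutation significance and Benjamini-Hochberg FDR control, and
    cross-validated ROC evaluation of biomarker panels. Includes a
    synthetic community generator with planted correlation modules and
    driver taxa so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vegan,
    igraph,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
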