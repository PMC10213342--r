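Package: gramcoord
Title: Spectral Coordination Analysis of a Chaperone Gene Panel Across
    Alzheimer's Disease Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify coordination within the BAG2-HSC70-STUB1-MAPT
    protein-folding network across Alzheimer's disease severity stages.
    Implements per-group uncentered Gram-matrix eigendecomposition of a
    four-gene panel (the leading eigenvalue fraction as a coordination
    statistic, with leading-direction alignment between stages), gene-wise
    two-sample differential-expression screening, a simplified soft-power
    weighted co-expression module stage with module eigengenes and
    module-trait correlation, a from-scratch 4-32-1 sigmoid feedforward
    network predicting MMSE from the panel, and a from-scratch RBF-mapped
    max-margin classifier with ROC/AUC. A synthetic-data generator plants
    every statistical structure the analysis assumes so the full pipeline is
    verifiable without external microarray downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust
Config/testthat/edition: 3
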