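Package: lncScreen
Title: Paired-Design lncRNA Biomarker Discovery and qPCR Panel Evaluation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for discovering and evaluating long
    noncoding RNA (lncRNA) diagnostic biomarkers from paired tumor/normal
    expression profiles. Covers quantile normalization and paired
    differential expression with Benjamini-Hochberg control, positional
    association of lncRNAs with coding genes, hypergeometric gene-set
    over-representation, a raw-intensity candidate-selection statistic,
    2^-deltadeltaCp relative quantification of qPCR crossing points, and
    ROC evaluation of single markers and logistic multi-marker panels on
    training and validation cohorts. Ships a synthetic-data generator with
    planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
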