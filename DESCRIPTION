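Package: trainomics
Title: Transcriptomic Analysis of Trained Immunity Kinetics in Splenic Myeloid Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of MARS-seq-style transcriptomics for trained
    immunity studies. Implements single-cell UMI count preprocessing (cell and
    gene QC, median library-size factors, log10 transformation, mean-CV
    noise-model variable-gene selection), PCA/KNN-graph/Louvain clustering with
    marker-based cluster annotation, bulk time-course processing with an
    integral-difference statistic for calling training-induced genes against a
    fitted normal null, two-sided t-test and one-way ANOVA differential
    expression with Benjamini-Hochberg FDR and fold-change filters, and
    hypergeometric over-representation analysis of gene lists against GMT
    collections. Ships synthetic single-cell and bulk kinetics generators with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
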