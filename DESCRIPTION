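Package: sccomm
Title: Microenvironment-Constrained Cell-Cell Communication and
    Transcription Factor Prioritization for Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers relevant ligand-receptor interactions between cell types
    from single-cell RNA-seq counts using a differential-expression-based
    retrieval rule with heteromeric-complex expression gates, enzyme proxies
    for non-peptide ligands, spatial microenvironment (shared-zone)
    constraints, and receptor-to-downstream-transcription-factor support
    annotation. Prioritizes transcription factors per cell type by combining
    three evidence layers: differential expression, regulon-based activity
    scores from target-gene expression, and motif-accessibility deviation
    scores from single-cell ATAC peaks. Ships a negative-binomial synthetic
    data generator with planted ground truth so the whole pipeline is
    testable end to end, plus readers and writers for the standard on-disk
    formats (Matrix Market, TSV, BED).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
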