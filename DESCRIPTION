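Package: mapuncert
Title: Per-Gene Read-Mapping Uncertainty Scoring for RNA-Seq Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the reliability of per-gene expression estimates
    derived from RNA-Seq read alignments. Multi-mapping reads (reads whose
    alignments tie at the best score across several genomic locations)
    inflate or deflate expression estimates for duplicated gene families.
    The package extracts a genomic feature (maximum sequence-similarity by
    match-length product), a transcriptomic feature (maximum shared
    multi-mapping read proportion) and a network feature (log-degree of
    significant partner locations) for every annotated gene, regresses an
    ambiguous-read proportion on them with elastic-net regularization to
    obtain a per-gene D-score, fits Gaussian and Gamma mixture models to
    the D-score distribution by k-means-initialized EM with BIC family
    selection, and classifies genes into Low, Medium and High
    mapping-uncertainty categories at the density-intersection cutoffs,
    with an alternative-likelihood confidence value per gene. Includes a
    synthetic-data generator (toy genomes with controlled duplications,
    GFF3 annotations and SAM alignments with ground-truth multiplicity)
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
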