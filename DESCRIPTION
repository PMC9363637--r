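Package: heterosisTx
Title: Mid-Parent Heterosis and Expression Inheritance-Mode Analysis for
    Reciprocal-Cross Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting heterosis in reciprocal-cross designs with
    two purebred parent lines and two F1 hybrid groups. Implements the
    mid-parent heterosis percentage (H%) with a one-sample significance test,
    a self-contained negative-binomial Wald test for differential expression
    with Benjamini-Hochberg correction, classification of features into the
    twelve inheritance bins and three inheritance patterns (additivity,
    dominance, overdominance), a long non-coding RNA identification cascade
    (length/strand/class-code filters, known-set matching, coding-potential
    consensus, positional classification, cis/trans target pairing), and a
    lightweight unsigned weighted co-expression network workflow (topological
    overlap, module detection, module eigengenes, module-trait correlation,
    top-edge export). Synthetic-data generators with planted ground truth
    provide recovery tests for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    jsonlite
Config/testthat/edition: 3
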