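Package: fusionscan
Title: Fusion-Transcript Discovery and Quantification from Paired-End RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of a chimeric-read strategy for
    discovering gene-fusion transcripts in bulk RNA-seq: a seeded synthetic
    genome and read generator with engineered fusion transcripts, a
    seed-and-extend split-read aligner, evidence aggregation with anchor,
    mismatch, locus-distance and support filters, in-frame fusion-protein
    prediction with domain retention, junction-spanning primer and siRNA
    design, and expression quantification (rpkm summaries and delta-delta-Ct
    relative expression with a positivity rule).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
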