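Package: eboxscreen
Title: Design and Analysis of CRISPR Screens Disrupting
    Transcription-Factor-Bound E-Boxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to design pooled CRISPR/Cas9 libraries that cut inside
    E-box motifs located in transcription-factor binding sites: motif
    scanning in merged ChIP-seq peaks with coding-exon exclusion,
    PAM-constrained guide enumeration, mismatch/seed-region off-target
    filtering, specificity scoring, and synthesis-oligo assembly. Also
    quantifies pooled screens from raw reads by exact protospacer
    matching, tests target-level depletion with a negative-binomial Wald
    model (median-of-ratios size factors, parametric dispersion trend,
    prior shrinkage), and analyses the strand-symmetrized flanking-sequence
    grammar of essential motifs. Seeded simulators for toy genomes,
    screen count matrices and amplicon FASTQ make the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    MASS,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    SummarizedExperiment,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
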