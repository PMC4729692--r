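Package: epistate
Title: Chromatin-State and Expression Analysis for Early Embryonic Epigenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for characterizing repressive chromatin
    states (H3K9me2/H3K27me3) and their transcriptional consequences in early
    mammalian development. Provides region-level ChIP enrichment
    quantification with k-means mark calling, a per-embryo Fisher-combined
    negative-binomial differential-expression procedure, repeat-subfamily
    regulation analysis, enhancer calling and epigenetic-state
    classification, self-organizing-map clustering of epigenetic signatures,
    and PWM motif enrichment against resampled genomic backgrounds. Includes
    seeded synthetic-data generators with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
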