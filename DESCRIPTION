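Package: circaprime
Title: Circadian Rhythm Detection in miRNA Primary Transcripts from
    Nascent Transcription Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects circadian miRNA primary transcripts from paired
    nascent-transcription time courses (GRO-seq / Nascent-seq style RPKM
    matrices) by 24-hour cosinor regression, a cross-dataset consistency
    score with permutation-based false discovery rate, and downstream
    analyses of miRNA over-expression experiments: two-way ANOVA target
    classification into circadian groups, enrichment statistics,
    relative-amplitude modulation, a first-order kinetic model of
    mature-miRNA amplitude attenuation, and construction of transcription
    factor / miRNA feed-forward regulatory motifs from ChIP peak calls.
    Ships a synthetic-data generator with planted ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    rtracklayer,
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
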