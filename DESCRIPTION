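Package: sigma54scope
Title: Sigma-54 Regulon Prediction, Variant Effects and Editing Arithmetic for Clostridial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consensus-motif prediction of sigma-54 (sigL) regulons in bacterial
    genomes by exact IUPAC scanning of both strands, upstream-window regulon
    assignment with operon extension and enhancer-binding-protein vicinity
    flagging; cross-strain regulon conservation via reciprocal-best-hit
    orthology; a point-mutation effect annotator (substitution, truncation,
    synonymous, intergenic); CRISPR deletion-design arithmetic (in-silico PCR
    band sizes, SpCas9 NGG protospacer enumeration, residual ORF length); and
    efficiency-corrected relative expression from RT-qPCR quantification
    cycles. A seeded synthetic-genome generator with stored ground truth makes
    every stage testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
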