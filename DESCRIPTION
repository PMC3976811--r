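Package: wrkyscan
Title: Genome-Wide Analysis of the WRKY Transcription Factor Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for genome-wide characterization of the WRKY
    transcription factor gene family. Detects WRKY domains with a
    sequence grammar (WRKYGQK heptapeptide variants plus C2H2 or C2HC
    zinc fingers), classifies genes into groups I/II/III and group II
    subgroups, flags pseudogenes, detects tandem and segmental gene
    duplications (70/70 coverage/identity rule) and 200-kb gene
    clusters, types conserved R- and V-type introns from exon
    structure, builds neighbor-joining trees with bootstrap support,
    and tests for selection with GY94 codon site models (M0, M3, M7,
    M8) and likelihood-ratio tests. Ships a curated table of the 71
    Lotus japonicus WRKY gene family members and a synthetic-genome
    generator with planted ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    Matrix,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
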