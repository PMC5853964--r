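Package: delscan
Title: Large Deletion Discovery from Exome-Capture Read Depth and
    Downstream Mutant Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers large chromosomal deletions in mutagenized polyploid
    genomes from binned exome-capture read depth normalized against a
    wild-type line, using run-length low-coverage criteria. Refines deletion
    borders against gene models, intersects homoeologous gene content across
    subgenomes, interprets dominant PCR-marker screens into deletion-extent
    hypotheses, quantifies Mendelian segregation of multi-locus deletion
    crosses, and measures starch-granule size distributions from micrographs
    by two-pass particle-area analysis. Includes simulators for every input
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    EBImage,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
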