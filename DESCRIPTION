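Package: lantimine
Title: Lanthipeptide Gene Cluster Mining and Mass-Ladder Dereplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the desk half of lanthipeptide (class I lantibiotic)
    discovery: six-frame open reading frame calling and conserved-motif scanning
    to locate biosynthetic gene clusters and their precursor peptides,
    electrospray-ionisation charge-state deconvolution of picked (m/z, z)
    signals to neutral average masses, and assignment of observed masses to
    N-terminally trimmed, dehydrated propeptide variants of a single precursor,
    including truncation-ladder inference from inter-mass residue differences
    and Edman N-terminal sequence constraints. A seeded synthetic-data
    generator produces gene clusters, precursors, product ladders and
    charge-state signals with known ground truth so every stage of the
    pipeline can be tested end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    BiocGenerics,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
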