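Package: ribostall
Title: Ribosome Profiling Stall-Site Detection and Elongation-Factor
    Loop Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of bacterial ribosome-profiling (Ribo-seq) libraries
    aimed at translational stalling: decomposition and UMI deduplication of
    raw footprint reads, contaminant filtering and unique exact mapping,
    A-site assignment by a fixed 3'-end offset, codon-resolution occupancy
    profiles and metagene curves, sliding-window fold-change pause calling,
    E/P/A-site amino-acid trimer enrichment, E-site codon nucleotide bias,
    asymmetry scores with elongation-factor dependency calls, and a
    classifier separating EF-P from EfpL family members by the length and
    tip residue of the KOW-domain beta3-omega-beta4 loop.  A footprint
    simulator with planted stall motifs, abortive drop-off and PCR
    duplicates provides fully specified synthetic libraries for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
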