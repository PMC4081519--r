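Package: rgkscan
Title: Signature-Based Discovery and Annotation of RGK-Family GTPases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying and annotating RGK-family small GTPases
    (Gem, Rad, Rem1, Rem2) and their invertebrate homologs from protein
    sequence sets. Implements compilation and scanning of PROSITE-like
    position-class patterns including the RGK C-terminal eleven-residue
    signature, G-motif-anchored extraction of the Ras-homology G-domain,
    a pattern-hit-initiated iterative position-specific scoring matrix
    (PSSM) search with a shuffle-based null model, per-column alignment
    conservation and differential-conservation scoring with sequence-logo
    information content, and a rule-based RGK-likeness classifier. A
    seeded synthetic-proteome generator produces benchmark sequence sets
    with planted motifs and truth tables so the full pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
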