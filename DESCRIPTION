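Package: plastomeRearr
Title: Plastome Structural Rearrangement Analysis with Inverted-Repeat Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of plastid genome (plastome) structural
    variation in lineages that have lost one copy of the large inverted
    repeat (IR). Detects IR and short inverted repeat (sIR) pairs, excises
    the redundant IR copy, encodes shared synteny blocks as signed
    permutations, computes exact signed reversal distances and optimal
    reversal scenarios via Hannenhalli-Pevzner breakpoint-graph theory,
    enumerates dispersed repeats under Hamming-distance criteria, quantifies
    read-pair evidence for sIR-mediated flip-flop isomers, and maps
    irreversible (Dollo) gene, intron, and IR losses onto a rooted
    phylogeny. Includes a seeded synthetic-plastome evolution module
    (quadripartite ancestors, scripted inversions, translocations, IR and
    gene loss, pseudogenization, paired-end read simulation) for fully
    reproducible desk-scale studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
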