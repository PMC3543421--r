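Package: mgecompare
Title: Comparative Genomics of Small Circular Mobile Genetic Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative analysis of small circular
    replicons such as archaeal plasmids and viruses. Predicts protein-coding
    ORFs on circular DNA with Shine-Dalgarno-guided start selection, locates
    candidate replication origins from cumulative GC skew and sequence
    repeats in large intergenic regions, clusters proteins into gene
    families by Smith-Waterman local alignment with identity and coverage
    thresholds, builds pan-genome presence/absence matrices, gene-content
    distance trees (neighbor-joining) and conservation-class maps, and
    cross-screens an external proteome (for example a viral one) against the
    plasmid pan-genome. Ships a synthetic replicon generator with planted
    ground truth (gene families, subfamily structure, origin position,
    repeats) so every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    withr,
    mclust
Config/testthat/edition: 3
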