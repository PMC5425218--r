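Package: enhancerscape
Title: Enhancer Landscapes, Super-Enhancer Calling and Regulatory
    Network Analysis for Keratinocyte Functional States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for histone-mark defined enhancer
    landscapes across cell states. Calls typical enhancers from
    overlapping H3K27ac/H3K4me1 peaks with an H3K4me3 fold-enrichment
    filter, calls super-enhancers by rank-curve geometry on stitched
    H3K27ac regions, classifies chromatin-state transitions between
    cell states, links enhancers to nearest genes and expression,
    tests disease-SNP enrichment in enhancers against size-matched
    random-region nulls, scans enhancer sequences with position
    weight matrices to build a directed TF-to-TF regulatory network,
    and scores knockdown-screen expression matrices with a weighted
    running-sum enrichment statistic. Ships a seeded synthetic-data
    generator that plants ground-truth enhancer landscapes, TF peaks,
    SNPs, motif instances and knockdown effects so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    optparse
Config/testthat/edition: 3
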