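Package: plastomics
Title: Comparative Analysis of Plastome Structure, Repeats, and Sequence
    Divergence
Version: 0.9.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for pairwise comparative analysis of
    chloroplast genomes (plastomes). Reads annotated plastomes from GenBank
    flat files, detects the quadripartite architecture (large and small
    single-copy regions separated by the inverted-repeat pair) and
    canonicalizes its orientation, censuses simple sequence repeats and
    dispersed (forward, palindromic, reverse) repeats, extracts and aligns
    syntenic loci to compute the sequence-variability (SV%) statistic for
    mutational-hotspot ranking, estimates pairwise dN/dS per gene by
    Nei-Gojobori codon counting with Jukes-Cantor correction, profiles
    IR/SSC junction architecture together with the ndh gene inventory
    (plastome types A/B/C) and fits the origin-constrained regression of IR
    boundary shift on retained ndh sequence length. A fully seeded synthetic
    plastome simulator with a complete planted-mutation ledger makes every
    analysis stage testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    Biostrings,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
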