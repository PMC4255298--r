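Package: orthoprofile
Title: Reciprocal-Best-Hit Orthology Profiling and Gene Gain/Loss Analysis
    for Bacterial Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference-anchored comparative genomics for bacterial genome
    collections: affine-gap local protein alignment, reciprocal-best-hit
    orthology calling with a three-state profile matrix, rare TTA (bldA
    target) codon scanning with a positional-bias test, local-synteny
    scoring of gene neighbourhoods, divergence profiling against a
    concatenated universal-protein control, one-way paralogue-family
    searches with neighbour-joining trees, and Dollo/Fitch parsimony
    reconstruction of gene gain and loss on a species phylogeny.  A
    genome-evolution simulator with full truth tables makes every stage
    verifiable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
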