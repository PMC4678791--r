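Package: cvphylo
Title: Alignment-Free Whole-Proteome Phylogeny from Composition Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds whole-proteome, alignment-free phylogenies for prokaryotes
    (and other taxa) from amino-acid K-peptide composition vectors with a
    (K-2)-th order Markov background subtraction, and compares the resulting
    tree branching order against a nine-rank reference taxonomy. Provides
    K-peptide counting, background-subtracted composition vectors, cosine
    dissimilarities, deterministic neighbor-joining, outgroup rooting,
    monophyly/convergence reporting with n + m accounting, rank-wise tree
    collapsing, lineage modification, a multi-K pipeline with a command-line
    entry point, and a seeded proteome simulator with known true phylogeny
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
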