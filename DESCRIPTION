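Package: rateshift
Title: Reference-Normalized Substitution-Rate-Shift Analysis for De Novo Gene Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether a genomic region changed its substitution
    rate at discrete evolutionary events, using the exons of flanking genes as a
    neutral-clock reference. Implements a piecewise-constant rate model on the
    four-taxon mammal phylogeny (((mouse,rat),human),dog) with two changepoints
    (a chromosomal inversion and the birth of a lncRNA gene), normalized average
    rates per species pair, algebraic recovery of stage-specific rate ratios,
    and the comparative-genomics stages around the model: a seeded phylogenetic
    sequence simulator, alignment filtering and concatenation, pairwise distance
    estimation (p, JC69, K80) with neighbor-joining trees, inversion detection
    from strand-flipped alignment blocks, RepeatMasker annotation parsing with
    transposable-element/feature overlap tables, and open-reading-frame scanning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
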