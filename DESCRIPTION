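Package: archnet
Title: Ordered Domain-Architecture Networks and Neighborhood-Linkage
    Statistics for the OST-HTH Superfamily
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of protein domain architectures,
    built around the OST-HTH (Oskar-TDRD5/TDRD7 helix-turn-helix) superfamily
    of predicted RNA-binding domains. Represents sets of ordered domain
    architectures as directed co-occurrence networks, computes the fraction
    of distinct architectures in which a focal domain has a neighbor of a
    given functional category (RNA-binding, anchoring, ubiquitin-system)
    within a positional distance, and tests that fraction against background
    domains by percentile or label-permutation methods. Also computes
    residue-class consensus lines over multiple alignments, phyletic
    presence/absence matrices across lineages, and synthetic architecture
    corpora and alignments with controlled linkage probabilities for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Biostrings,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
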