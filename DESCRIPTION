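Package: archevol
Title: Comparative Evolution of Genome Architecture Across Species Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analyses of genome architecture evolution across a rooted
    species tree: pairwise microsynteny conservation from single-copy
    ortholog collinearity with a permutation null and a normalized synteny
    ratio; intron-site mapping onto protein alignments and probabilistic
    gain/loss reconstruction under a two-state Markov model with
    branch-specific rates; protein domain architecture decomposition into
    directed domain pairs, ancestral pair reconstruction, Dollo parsimony
    for single domains, and domain co-occurrence networks with Louvain
    community structure, modularity, and degree-preserving rewiring nulls;
    transposable-element landscape statistics (family saturation, identity
    profiles); and coding-sequence conservation comparisons from cophenetic
    gene-tree distances. A synthetic-data generator with recorded ground
    truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    graphics,
    rtracklayer,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
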