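Package: rnaphylo
Title: RNA Sequence-Structure Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Phylogenetic inference from RNA sequences together with their
    secondary structures. Provides template-based homology modeling of
    secondary structure (base-pair transfer through pairwise alignment with
    transfer-percentage filtering), a 12-letter encoding of nucleotide plus
    pairing state, structure-aware pairwise and progressive multiple
    alignment under 12x12 scoring matrices, 12-state evolutionary distances
    (p, generalized Jukes-Cantor, maximum likelihood under a loadable rate
    matrix with gamma rate heterogeneity and invariant sites), tree inference
    by neighbor-joining, iterated profile neighbor-joining with bootstrap
    super-profiles, Fitch parsimony and 12-state maximum likelihood, plus
    annotation of canonical internal transcribed spacer 2 (ITS2) structural
    hallmarks and a fully seeded synthetic-data generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
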