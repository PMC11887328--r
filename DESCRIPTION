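Package: kmerphylo
Title: Alignment-Free Phylogenies from k-mer Presence/Absence Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates phylogenetic trees from unaligned genome sequences.
    Each taxon's genome is reduced to its set of k-mers (canonical or
    strand-specific), the sets are assembled into a binary presence/absence
    matrix, and the k-mer length is chosen by maximizing the cumulative
    Shannon entropy of sampled matrix rows. The selected matrix is analysed
    under a reversible two-state substitution model with discrete-gamma rate
    heterogeneity: Felsenstein-pruning likelihood, branch-length and shape
    optimization, neighbor-joining start trees, nearest-neighbor-interchange
    hill climbing, nonparametric bootstrap and majority-rule consensus.
    Includes Robinson-Foulds tree comparison and simulators for trees, DNA
    sequences and binary characters so every stage can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
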