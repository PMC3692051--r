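Package: rankmotif
Title: De Novo Discovery of Rank-Imbalanced Sequence Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Finds short sequence motifs (DNA, RNA or protein) that are
    over-represented at the top of a ranked list of sequences. Candidate
    k-mers are enumerated from a generalized suffix tree built with
    Ukkonen's algorithm, scored with the minimum-hypergeometric (mHG)
    statistic whose top/rest cutoff is chosen in a data-driven way, and
    assigned exact p-values by dynamic programming. Significant k-mers are
    greedily extended into position-specific scoring matrices (PSSMs) via
    Hamming neighbors. Supports single- and double-strand search, a
    target-versus-background mode with fixed-cutoff hypergeometric tests,
    planted-motif simulation utilities, tabular and JSON reporting, and a
    command-line driver script.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
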