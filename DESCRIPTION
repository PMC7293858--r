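Package: writhescan
Title: Writhe of All Protein Sub-Chains and Rare-Conformation Searches
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the writhe (order-1 Gauss integral) of every
    contiguous sub-chain of a protein C-alpha trace with an O(L^2)
    inclusion-exclusion recursion, and derives the mutual writhe of any two
    disjoint sub-chains in constant time from the stored writhe table.  On
    top of the table it implements a restricted search for pre-defined
    topologic-geometric motifs (1-links and pokes built from almost-closed
    loops), an unrestricted search for extreme-writhe window pairs (knots,
    pseudo-knots, multi-winds), and a rarity scan (rar0) that ranks query
    structures against a background set by one-sided empirical exceedance
    probabilities of their extreme mutual writhe.  Includes a PDB reader
    producing clean C-alpha traces, synthetic polygonal-curve generators
    (Hopf links, helices, zigzags, seeded random walks) with known
    topology, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
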