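Package: ciperc
Title: Collective Influence Algorithms for Optimal Percolation and Network Immunization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds minimal sets of influential nodes in undirected networks via
    optimal percolation. Implements the adaptive Collective Influence (CI)
    attack with an indexed max-heap and localized score updates, the
    non-backtracking eigenvalue stopping rule, greedy reinsertion for budgets
    below the percolation threshold, the high-degree-adaptive baseline,
    Collective Influence Propagation (left/right non-backtracking message
    passing), and an SIR belief-propagation immunization algorithm whose
    zero-seed, certain-transmission limit recovers optimal percolation.
    Includes Erdos-Renyi and random-regular graph generators, edge-list and
    attack-trace input/output, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
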