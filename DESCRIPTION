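Package: stripekit
Title: Graph-Based Architectural Stripe Calling and Loop-Extrusion Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Calls architectural stripes from sparse chromatin-loop sets
    (BEDPE) by building an interaction graph over merged loop anchors and
    scoring anchored chains of leaves with rank-based gap statistics.
    Includes tolerance-aware overlap statistics for loops, stripes and
    striping domains, enhancer-promoter loop annotation, probabilistic CTCF
    motif orientation at anchors, a two-population stochastic loop-extrusion
    simulator with orientation-dependent barriers and simulated annealing,
    and a deterministic synthetic-fixture generator with planted stripes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
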