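Package: dialectsim
Title: Contact-Based Simulation of Cognate Evolution on Dialect Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolution of basic-vocabulary cognates on spatial
    dialect networks in which lexical items spread through contact rather than
    through branching descent. Dialects are nodes of a weighted undirected
    graph; at each discrete time step every node resamples its cognate set
    for a concept from an exponential-family distribution over the non-empty
    subsets of locally available candidates, with influence weights derived
    from neighbor populations and distances. The package converts simulated
    snapshots into binary character matrices, computes Hamming-ratio distance
    matrices, summarizes cognate survival times, measures tree-likeness with
    the quartet-based delta score, and exports NEXUS/PHYLIP/CSV files for
    downstream phylogenetic software. Five ready-made network topologies
    (grid, star, two stars, bottleneck, colony) are shipped as editable
    configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    phangorn,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
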