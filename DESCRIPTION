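Package: medianmix
Title: Ancestral Gene Order Inference by Mixing Adjacency Likelihoods
    with Constrained Median Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs ancestral gene orders of circular unichromosomal
    genomes evolving by inversions on a fixed phylogeny. A two-state
    likelihood model yields posterior probabilities for every candidate gene
    adjacency at an internal node; an exact DCJ median solver (branch and
    bound on the multiple breakpoint graph, accelerated by adequate-subgraph
    shrinking and adjacency-fixing edge surgery) refines them; a randomized
    mixture procedure repeatedly fixes random subsets of the
    likelihood-proposed adjacencies in constrained median searches, ranks
    adjacencies by how often the medians recover them, and fixes the
    best-supported fraction in a final median computation. Includes an
    inversion simulator on uniform and diameter-controlled random trees and
    an evaluation harness measuring adjacency accuracy against known
    simulated ancestors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
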