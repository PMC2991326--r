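Package: ppideconv
Title: Direct Protein Interaction Inference from AP-MS Connectivity Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Separates direct (physical) protein-protein interactions from
    indirect ones in affinity-purification mass-spectrometry (AP-MS) data.
    Models the hidden direct-interaction network as a probabilistic graph in
    which every direct interaction survives the purification independently
    with probability p-hat, so that observed co-purification frequencies
    estimate pairwise two-terminal connection probabilities. Provides
    Monte-Carlo and exact two-terminal reliability, recursive cut-edge and
    degree-2 vertex detection from the connectivity matrix, clique-threshold
    dense-region discovery, instance reduction with meta-edge contraction of
    forced parallel paths, and a cut-based genetic algorithm that infers the
    densely connected residual of the network. Includes scale-free network
    generators (preferential attachment and duplication models), a
    randomized hill-climbing baseline, and a peptide-count front end that
    turns bait-prey spectral counts into a connectivity matrix via a
    logistic map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
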