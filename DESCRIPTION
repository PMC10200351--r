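Package: ktnreduce
Title: Partial Graph Transformation for Ill-Conditioned Kinetic Transition Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dimensionality reduction of continuous-time Markov chains on
    kinetic transition networks by partial graph transformation: states are
    eliminated and the branching probabilities, waiting times, rates and
    stationary distribution of the retained states are renormalized exactly,
    preserving mean first-passage times and absorption probabilities.
    Community boundary nodes and the maximum-occupation node of each
    community are retained, which keeps first-passage-time distributions
    accurate in the metastable regime. Includes spectral first-passage
    analysis of absorbing subsystems (eigendecomposition via a symmetric
    similarity transform for reversible chains), rejection-free kinetic
    Monte Carlo and absorbing-Markov-chain basin-escape samplers, a
    generator of multi-well model landscapes with Arrhenius rates obeying
    detailed balance, and effective-free-energy and disconnectivity-graph
    output for reduced networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
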