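Package: boolpop
Title: Stochastic Boolean Networks with Cell-Population Dynamics and
    Network-Control Target Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of logical (Boolean) models of
    intercellular signalling as continuous-time Markov chains, in the
    MaBoSS textual dialect, with a population layer in which trajectories
    carrying an active Division node double their probability mass, those
    carrying Death are removed, and receptor activation rates are
    recomputed each synchronous step from ligand probabilities (UPMaBoSS
    semantics). Includes chained untreated/perturbed simulations with a
    percent-response statistic, one-at-a-time parameter sensitivity
    scans, feedback-vertex-set enumeration of the signed influence graph,
    and drug-target-pair ranking by three network-propagation metrics
    (PRINCE, modified PRINCE, CheiRank). Ships a synthetic-model
    generator producing analytically solvable test cases and toy
    multiscale disease models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    deSolve,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
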