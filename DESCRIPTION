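Package: metamem
Title: Evolving Metamemory in Neuromodulated Recurrent Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying the evolution of metamemory in
    artificial agents. Provides a recurrent neural network with neuromodulated
    (second-order) synaptic plasticity driven by an extended Hebbian rule, a
    delayed match-to-sample task environment with an escape (decline) option
    and an unsolvable condition, and a genetic algorithm with segmented
    selection, submatrix crossover and structural (insert/delete/duplicate)
    neuron operators. Behavioral assays summarise forced, chosen and
    declined-counterfactual test accuracy by stimulus pattern and delay, and a
    trace recorder logs activations, modulatory signals and weight trajectories
    for mechanism-level inspection of evolved networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
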