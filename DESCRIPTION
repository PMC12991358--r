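Package: iafphi
Title: Integrated Information of Leaky Integrate-and-Fire Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates small networks of leaky integrate-and-fire neurons,
    coarse-grains their activity to binary spike states, estimates empirical
    state-by-state transition probability matrices, and computes integrated
    information (big Phi) under Integrated Information Theory 3.0, including
    cause/effect repertoires, earth-mover's-distance irreducibility measures
    and unidirectional system cuts. Provides logic-gate network presets
    (OR-AND-XOR), membrane-time-constant by synaptic-weight parameter sweeps,
    Poisson noise-injection experiments, and ggplot2 visualisations of traces
    and Phi matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
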