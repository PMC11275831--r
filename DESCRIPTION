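Package: ncamorph
Title: Neural Cellular Automata for In Silico Morphogenesis Under
    Developmental Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates morphogenesis as a neural cellular automaton (NCA):
    a fixed grid of cells, each running an identical permutation-invariant
    neural controller, collectively self-assembles a target cell-type
    pattern over a fixed number of noisy developmental steps. Genomes are
    split into a structural part (initial cell states), a functional part
    (controller weights) and an optional competency gene decoding to the
    per-cell decision-making probability. Provides the developmental
    rollout engine (with a pure-R reference implementation), the
    phenotype-based fitness score with pattern-maintenance reward and
    stagnation penalty, a covariance matrix adaptation evolution strategy
    (CMA-ES) neuroevolution driver with warm-starting, and experiment
    harnesses for encoding comparisons, competency/noise/redundancy
    sweeps, generalization rollouts and transfer studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
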