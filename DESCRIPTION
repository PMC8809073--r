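Package: lazywalks
Title: Lazy Random Walks on Graphs: Social Distancing, Gathering and Search Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact and simulated analysis of teams of agents performing lazy
    random walks on small graphs (lines, cycles, grids, custom edge lists).
    Builds the absorbing Markov chain induced by synchronous independent
    moves for three goals: social distancing (all pairwise graph distances
    at least D), sticky gathering (multi-rendezvous with coalescence) and
    searcher-hider capture. Computes fundamental matrices, expected
    absorption times and absorption probabilities, exploits cycle symmetry
    to lump states into gap-coordinate classes, and carries transition
    matrices symbolically in the laziness parameters so that absorption
    times are exact rational functions. On top of the chain machinery it
    optimises scalar and population-dependent laziness, solves the
    two-searcher/one-hider team game (saddle point of expected capture
    time) and competitive search equilibrium on the triangle, analyses the
    first-to-disperse game on the line, and cross-validates everything with
    a seeded Monte Carlo engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
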