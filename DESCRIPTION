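Package: exclusim
Title: Spatial Stochastic Simulation of Contact Inhibition in Tumor-Normal
    Cell Co-Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a discrete-time Markov chain on admissible lattice
    configurations of two interacting cell types (tumor and normal) subject to
    hard-core type-pair exclusion distances, a Widom-Rowlinson-type model of
    contact inhibition. Provides exact per-vertex update distributions, a fast
    compiled simulation kernel with division, migration and death events,
    admissible initial-configuration generators, occupancy heatmaps, cluster
    morphometrics (area, perimeter, convexity, aspect ratio) with pixel-to-
    micrometre conversion, cell-to-cell distance distributions, density-by-
    distance-band profiles with exponential decay fits, logistic growth-curve
    fitting, and a command-line interface for scripted in-silico experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    igraph,
    jsonlite,
    yaml,
    minpack.lm,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
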