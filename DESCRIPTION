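Package: ifsgene
Title: Stochastic Gene Expression as an Iterated Function System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a discrete-time stochastic model of
    gene expression with three molecular stages (pre-mRNA, mRNA, protein) and
    a randomly switching gene on/off state.  Between switches the molecule
    levels follow a linear system of difference equations with a closed-form
    solution; the switching is driven either by place-dependent map-selection
    probabilities (an iterated function system with place-dependent
    probabilities) or by state-dependent jump intensities through a discrete
    life-span function.  The package provides the deterministic flow and its
    geometric-mode decomposition, the two affine contraction maps in reduced
    coordinates, chaos-game and Hutchinson-iteration attractor sampling,
    Markov/transfer operators on empirical measures with convergence
    diagnostics, the closed-form parametric geometry of the invariant set, and
    a small command-line interface for reproducible simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
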