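Package: viadeco
Title: Viability-Space Decomposition for Dynamical Cell Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing survival outcomes in dynamical models of cells.
    A viability region - the set of states in which a model cell is alive - is
    decomposed into asymptotically viable states (trajectories that remain
    viable and converge to a viable attractor) and transiently viable states
    (trajectories that violate a constraint in finite time). The package
    computes the organizing structures of this decomposition: mortality
    manifolds seeded at boundary tangencies, ordering manifolds seeded at
    joint-fatal corners where several constraints are violated simultaneously,
    and collapse manifolds that extend organizing structures of a reduced
    post-death system backward into the pre-death state space. Multicellular
    death cascades are simulated as hybrid dynamical systems over a directed
    configuration graph whose nodes are alive-cell subsets and whose edges are
    death events. A Game-of-Life engine derives the intrinsic viability
    partition of the glider: configurations are classified as interior,
    boundary, or nonmember according to whether the glider's identity survives
    its interactions with environmental perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    optparse
Config/testthat/edition: 3
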