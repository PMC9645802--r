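Package: tetsim
Title: Stochastic Reaction-Diffusion and Membrane Potential Simulation on
    Tetrahedral Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An operator-splitting simulator for spatial stochastic
    reaction-diffusion systems on tetrahedral meshes, coupled to a
    deterministic membrane-potential solver.  Chemical kinetics are sampled
    exactly within short time windows by the Gibson-Bruck next-reaction
    variant of the Gillespie stochastic simulation algorithm, molecules are
    redistributed between mesh elements by a windowed stochastic diffusion
    operator, and the transmembrane voltage is advanced by a backward-Euler
    finite-element step with ohmic and Goldman-Hodgkin-Katz channel
    currents.  The package includes Gmsh MSH mesh import/export, structured
    mesh generators, an emulation of distributed-memory partitioning with
    ghost layers and staged state synchronization, the Rallpack benchmark
    fixtures (passive cable and stochastic Hodgkin-Huxley axon), and a
    statistical validation toolkit based on batched two-sample
    Cramer-von Mises tests and confidence-band comparison of trace
    ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
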