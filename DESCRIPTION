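Package: perfusim
Title: Cell and Matrix Growth Simulation in Perfusion Bioreactor Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Homogenized (space-independent) simulation of mesenchymal
    stromal cell proliferation and extracellular-matrix production inside a
    3D porous scaffold cultured in a perfusion bioreactor. The six-variable
    ODE model couples oxygen, glucose and lactate kinetics
    (Michaelis-Menten), pH inhibition, flow-induced shear and interface
    curvature closures, and a decaying growth factor that differentially
    stimulates proliferation over matrix deposition. Discrete
    medium-refreshment events are handled with hard integrator restarts.
    Includes a genetic-algorithm calibration of the growth and
    growth-factor-response constants against observed cell/ECM time
    courses (with a synthetic-observation generator for parameter-recovery
    testing), an anchor-based normalization of the lumped rate scales, an
    experiment cost model, Pareto-dominance utilities, a multi-objective
    particle swarm optimizer over refreshment regimens and growth-factor
    dose, and knee-point (sweet spot) selection on the Pareto front.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
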