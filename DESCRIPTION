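Package: cellsqueeze
Title: Coupled Lattice-Boltzmann / Spring-Network Simulation of Cell
    Passage Through Microfluidic Constrictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a deformable cell travelling through a microfluidic
    constriction by coupling a D3Q19 lattice-Boltzmann fluid solver to a
    Kelvin-Voigt spring-network membrane model (neo-Hookean edge springs,
    dihedral bending, local/global area and volume constraints), with
    node-wall repulsion and a velocity-opposing kinetic friction force.
    Includes a genetic-algorithm identification procedure that recovers the
    viscoelastic moduli and per-flow-rate surface friction coefficient from
    entry-time and transit-time observations, an optical-tweezers stretch
    scenario for red blood cell validation, synthetic fixture generators for
    closed-loop testing, and legacy VTK / CSV writers for inspection of the
    simulated fields.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tibble,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
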