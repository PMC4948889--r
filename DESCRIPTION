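Package: rcnsim
Title: Kinetic Simulation of the Wnt/Beta-Catenin, N-Glycosylation and
    E-Cadherin Adhesion Regulatory Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for a regulatory cell network coupling Wnt/beta-catenin
    signaling, DPAGT1-driven protein N-glycosylation, and E-cadherin-mediated
    cell-cell adhesion in epithelial (MDCK-like) cells. Encodes a 26-process
    reaction scheme reduced by rapid-equilibrium and conservation arguments to a
    system of 15 ordinary differential equations and 9 algebraic relations, with
    per-pool E-cadherin adhesivity factors driven by Michaelis-Menten
    N-glycosylation kinetics. Provides steady-state and Wnt-activation time
    courses, fold-change analysis, local sensitivity analysis with global
    parameter ranking, condition presets (reference and ICG-001-like
    dysregulation), constraint-based parameter checking and fitting, and
    collective-motility metrics (lateral velocity correlation length,
    movement-angle occupancy maps, leading-edge speed) for PIV-derived velocity
    fields, together with seeded synthetic-data generators for all input kinds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
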