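Package: bindstates
Title: Binding Kinetics and Oligomeric-State Evidence for Protein Complexes
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative inference chain for characterising a small
    GTPase-effector interaction and its oligomeric state in solution:
    global kinetic fitting and model discrimination of biolayer
    interferometry (BLI) sensorgrams under 1:1, 2:1 heterogeneous-ligand
    and 1:2 bivalent-analyte schemes; NMR chemical shift perturbation and
    intensity fold-change analysis of HSQC titrations with exact two-state
    fast-exchange arithmetic; Lipari-Szabo model-free fitting of 15N
    relaxation data and Stokes-Einstein-Debye hydrodynamic predictions to
    discriminate dimer from tetramer; Gaussian-mixture fitting of mass
    photometry event lists with oligomer mass-ladder assignment; and
    contact detection (hydrogen bonds, salt bridges, hydrophobic contacts)
    at two-chain structure interfaces. Seeded synthetic-data generators
    emulate every input modality so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
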