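Package: minfibril
Title: Mesoscale Simulation of Mineralized Collagen Fibril Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained molecular-dynamics simulator for a single
    mineralized collagen fibril. Builds quarter-staggered fibril models with
    tunable intrafibrillar hydroxyapatite content and enzymatic crosslinks,
    evaluates a breakable bilinear-bond / harmonic-angle / Lennard-Jones
    force field, runs Langevin dynamics with axial box relaxation and
    strain-controlled tensile tests, and analyses the resulting
    stress-strain response (deformation regimes, moduli, toughness,
    mineral-induced contraction, internal stress, broken-bond statistics).
    Particle systems are read and written in the LAMMPS data dialect;
    trajectories as LAMMPS-style dumps or XYZ.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
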