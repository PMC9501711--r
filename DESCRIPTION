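Package: dockfit
Title: Torsion Force-Field Fitting and Docking Post-Analysis for
    Catecholamine-Receptor Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational chain used to parameterize and
    validate small-molecule torsional force fields and to post-process
    receptor-ligand docking results.  Covers subtraction of intramolecular
    electrostatic and Lennard-Jones energy from quantum-mechanical torsional
    scans and fitting of the residual with an OPLS-style cosine series;
    Boltzmann inversion of dihedral-angle distributions into Helmholtz
    free-energy profiles; greedy energy-ranked clustering of docking pose
    ensembles with run-consistency checks; interconversion of binding free
    energy, inhibition constant and binding affinity (pKd); and geometric
    protein-ligand interaction profiling (hydrogen-bond compatibility,
    hydrophobic contacts, residue contact fractions).  Seeded synthetic-data
    generators emulate every input class (torsional scans, dihedral
    trajectories, pose ensembles, binding sites) with known ground truth so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
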