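Package: ensrepack
Title: Ensemble-Based Enzyme Design by Targeted Ligand Placement and
    Simulated-Annealing Repacking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for physics-based computational enzyme design over single
    or ensemble backbone templates. Provides a PDB structure and multi-MODEL
    ensemble reader with alternate-location conformer policies, a
    backbone-independent rotamer library loader with plus/minus one standard
    deviation chi-angle expansion, a pairwise-decomposable scoring function
    (Lennard-Jones 12-6, directional hydrogen bonds, screened Coulomb,
    occlusion solvation, secondary-structure propensity, and
    contact-geometry bias), targeted transition-state ligand placement with
    rigid-body perturbation grids, Monte Carlo simulated-annealing side-chain
    repacking against an all-glycine reference, ensemble-template design
    drivers, and crystallographic B-factor Z-score heterogeneity analysis
    with mutation-set and catalytic-efficiency bookkeeping.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
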