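# Shared fixtures, all generated in code.

toy_params <- energy_parameters()
toy_scaffold <- make_toy_scaffold(fixture_spec(seed = 1))
toy_ligand <- make_toy_ligand()
toy_rotlib <- make_toy_rotamer_library()

# Generic carboxylate-like H-bond contact anchored on residue 1 of the toy
# scaffold, pointing the ligand acceptor into the pocket.
toy_contact <- contact_spec(c("A/1/N", "A/1/CA", "A/1/CB"),
                            c("O7", "C1", "C2"),
                            distance = c(2.8, 0.4),
                            angles = list(c(120, 20)),
                            dihedrals = list(c(180, 30)))

toy_pose_library <- function(scaffold = toy_scaffold, dof_grids = NULL) {
  generate_poses(scaffold, toy_ligand, list(toy_contact), dof_grids, toy_params)
}

# Free-standing backbone triad for side-chain building.
toy_backbone <- data.frame(name = c("N", "CA", "C"),
                           x = c(-1.45, 0, 1.0), y = c(0, 0, 1.1),
                           z = c(0.2, 0, 0),
                           element = c("N", "C", "C"),
                           stringsAsFactors = FALSE)

residue_from_sidechain <- function(bb, sc) {
  rbind(bb[, c("name", "x", "y", "z")], sc[, c("name", "x", "y", "z")])
}

# Hand-written 5-atom PDB fixture (fixed-column records).
five_atom_pdb <- c(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 11.50           C",
  "ATOM      3  C   ALA A   1      12.795   7.058  -4.968  1.00 12.00           C",
  "ATOM      4  O   ALA A   1      13.123   7.830  -5.872  1.00 13.25           O",
  "ATOM      5  CB  ALA A   1      10.521   6.351  -4.129  1.00 14.00           C",
  "END")

# Altloc fixture: residue 1 with A/B conformers for CB.
altloc_pdb <- function(occ_a = 0.60, occ_b = 0.40) c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
  "ATOM      3  C   ALA A   1       2.000   1.420   0.000  1.00 10.00           C",
  "ATOM      4  O   ALA A   1       1.300   2.400   0.100  1.00 10.00           O",
  sprintf("ATOM      5  CB AALA A   1       2.000  -0.800   1.200%6.2f 10.00           C", occ_a),
  sprintf("ATOM      6  CB BALA A   1       2.000  -0.800  -1.200%6.2f 10.00           C", occ_b),
  "END")

# Multi-MODEL text built from a structure.
as_ensemble_text <- function(model, n = 3L) {
  body <- write_structure(model)
  body <- body[body != "END"]
  out <- character(0)
  for (i in seq_len(n))
    out <- c(out, sprintf("MODEL %8d", i), body, "ENDMDL")
  c(out, "END")
}

# Random interaction matrices for search-vs-oracle checks.
random_matrix <- function(n_choices, seed, scale = 3) {
  set.seed(seed)
  np <- length(n_choices)
  ob <- lapply(n_choices, function(n) rnorm(n, sd = scale))
  tb <- list()
  if (np > 1L) {
    for (i in seq_len(np - 1L)) {
      for (j in seq(i + 1L, np)) {
        tb[[length(tb) + 1L]] <- list(
          i = i, j = j,
          mat = matrix(rnorm(n_choices[i] * n_choices[j], sd = scale),
                       n_choices[i], n_choices[j]))
      }
    }
  }
  structure(list(positions = paste0("p", seq_len(np)), n_choices = n_choices,
                 one_body = ob, two_body = tb, constant = 0),
            class = "interaction_matrix")
}

# 1-D golden-section minimiser (independent oracle for energy argmins).
golden_min <- function(f, lo, hi, tol = 1e-9) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  while (abs(b - a) > tol) {
    if (f(c1) < f(d1)) b <- d1 else a <- c1
    c1 <- b - gr * (b - a)
    d1 <- a + gr * (b - a)
  }
  (a + b) / 2
}
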