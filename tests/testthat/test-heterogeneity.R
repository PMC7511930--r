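three_atom_model <- function(b = c(10, 20, 30)) {
  atoms <- data.frame(record = "ATOM", serial = 1:3,
                      name = c("CB", "CG", "CD"), altloc = "",
                      res_type = "GLN", chain = "A", resno = c(1L, 1L, 2L),
                      ins = "", x = c(0, 2, 4), y = 0, z = 0, occ = 1, b = b,
                      element = "C", is_h = FALSE, stringsAsFactors = FALSE)
  structure(list(model_id = 1L, source_tag = "single", atoms = atoms,
                 ligand = atoms[0, ], waters = atoms[0, ]),
            class = "structure_model")
}

test_that("Z-scores use the population standard deviation", {
  rep <- bfactor_zscores(three_atom_model(c(10, 20, 30)))
  # population sd of {10,20,30} is sqrt(200/3); hand arithmetic
  expect_equal(rep$atoms$z, c(-10, 0, 10) / sqrt(200 / 3), tolerance = 1e-9)
  expect_equal(rep$atoms$z[2], 0)  # B at the mean has z = 0
  expect_error(bfactor_zscores(three_atom_model(c(15, 15, 15))),
               "degenerate population")
})

test_that("Z-score populations have mean 0 and sd 1", {
  m <- make_synthetic_bfactors(toy_scaffold,
                               fixture_spec(seed = 5, bfactor_loop_inflation = 2,
                                            bfactor_noise_sd = 1.5))
  for (pop in c("sidechain", "all")) {
    rep <- bfactor_zscores(m, pop)
    expect_lt(abs(mean(rep$atoms$z)), 1e-9)
    expect_lt(abs(sqrt(mean(rep$atoms$z^2)) - 1), 1e-9)
  }
})

test_that("Z-scores are invariant under affine B-factor transforms", {
  m <- make_synthetic_bfactors(toy_scaffold,
                               fixture_spec(seed = 9, bfactor_loop_inflation = 3,
                                            bfactor_noise_sd = 2))
  z0 <- bfactor_zscores(m)$atoms$z
  for (ab in list(c(2, 0), c(1, 7), c(0.3, -2))) {
    m2 <- m
    m2$atoms$b <- pmax(ab[1] * m$atoms$b + ab[2], 0)
    expect_equal(bfactor_zscores(m2)$atoms$z, z0, tolerance = 1e-9)
  }
})

test_that("only the highest-occupancy conformer enters the statistics", {
  m <- three_atom_model()
  alt <- m$atoms[1, ]
  alt$altloc <- "B"; alt$occ <- 0.4; alt$b <- 500
  m$atoms$altloc[1] <- "A"; m$atoms$occ[1] <- 0.6
  m$atoms <- rbind(m$atoms, alt)
  rep <- bfactor_zscores(m)
  expect_equal(nrow(rep$atoms), 3L)
  expect_false(500 %in% rep$atoms$b)
})

test_that("per-residue means average side-chain heavy atoms, Gly excluded", {
  m <- make_synthetic_bfactors(toy_scaffold, fixture_spec(seed = 2))
  # poly-Ala: every residue contributes its CB only
  m$atoms$b <- seq_len(nrow(m$atoms))  # arbitrary spread
  rep <- bfactor_zscores(m)
  expect_equal(nrow(rep$residues), 16L)
  expect_true(all(rep$residues$n_atoms == 1L))
  # residues mutated to Gly drop out of the per-residue table
  g <- m
  g$atoms$res_type[g$atoms$resno == 3] <- "GLY"
  g$atoms <- g$atoms[!(g$atoms$resno == 3 & g$atoms$name == "CB"), ]
  rep_g <- bfactor_zscores(g)
  expect_equal(nrow(rep_g$residues), 15L)
  expect_false(3 %in% rep_g$residues$resno)
})

test_that("cross-chain averaging pairs residues and flags singletons", {
  m <- three_atom_model(c(10, 20, 30))
  bchain <- m$atoms
  bchain$chain <- "B"
  m2 <- m
  m2$atoms <- rbind(m$atoms, bchain)
  m2$atoms$b <- c(10, 20, 30, 20, 30, 40)
  rep <- bfactor_zscores(m2)
  avg <- average_over_chains(rep)
  byres <- split(rep$residues$mean_z, rep$residues$resno)
  expect_equal(avg$mean_z, vapply(byres, mean, 0), ignore_attr = TRUE)
  expect_true(all(avg$n_chains == 2L))
  expect_false(any(avg$single_chain))
  # identical B profiles across chains: averages equal per-chain values
  m3 <- m2
  m3$atoms$b <- c(10, 20, 30, 10, 20, 30)
  rep3 <- bfactor_zscores(m3)
  avg3 <- average_over_chains(rep3)
  expect_equal(avg3$mean_z,
               rep3$residues$mean_z[rep3$residues$chain == "A"],
               ignore_attr = TRUE)
  # single-chain structures pass through with the flag set
  avg1 <- average_over_chains(bfactor_zscores(m))
  expect_true(all(avg1$single_chain))
})

test_that("a synthetic rigidified-loop profile is recovered with correct signs", {
  m <- make_synthetic_bfactors(toy_scaffold,
                               fixture_spec(seed = 3, bfactor_loop_inflation = 3))
  loop <- attr(m, "loop_resno")
  rep <- bfactor_zscores(m)
  in_loop <- rep$residues$resno %in% loop
  expect_gt(min(rep$residues$mean_z[in_loop]),
            max(rep$residues$mean_z[!in_loop]))
  expect_true(all(rep$residues$mean_z[in_loop] > 0))
  expect_true(all(rep$residues$mean_z[!in_loop] < 0))
  # inflation 1 gives no contrast (degenerate single-level population)
  flat <- make_synthetic_bfactors(toy_scaffold,
                                  fixture_spec(seed = 3, bfactor_loop_inflation = 1))
  expect_error(bfactor_zscores(flat), "degenerate")
})

test_that("mutation tokens parse, count, annotate and round-trip", {
  hg <- hg_series_mutations()
  row <- function(v) hg[hg$variant == v, ]
  hg317 <- parse_mutations(row("HG3.17")$mutations,
                           design_sites = strsplit(row("HG3.17")$design_sites,
                                                   " ")[[1]])
  hg4 <- parse_mutations(row("HG4")$mutations)
  expect_length(hg317, 17L)
  expect_length(hg4, 8L)
  expect_length(mutation_set_difference(hg317, hg4), 9L)
  expect_length(mutation_set_difference(hg4, hg4), 0L)
  expect_equal(count_annotated(hg317), 8L)
  expect_equal(count_annotated(hg4), 0L)  # no flags attached
  all_flagged <- parse_mutations("K50Q G82A", design_sites = c(50, 82))
  expect_equal(count_annotated(all_flagged), 2L)
  expect_length(parse_mutations(""), 0L)
  expect_identical(parse_mutations(format_mutations(hg317))$tokens$token,
                   hg317$tokens$token)
  # disjoint sets leave the left side unchanged
  other <- parse_mutations("S265T")
  expect_equal(format_mutations(mutation_set_difference(hg4, other)),
               format_mutations(hg4))
  expect_error(parse_mutations("K50"), "malformed")
  expect_error(parse_mutations("K50Q K50H"), "duplicate")
  expect_error(parse_mutations("X50Q"), "invalid amino-acid")
})

test_that("fit_efficiency recovers slopes exactly and under noise", {
  kd <- make_synthetic_kinetics(fixture_spec(seed = 1, kinetics_slope = 1e5,
                                             kinetics_noise = 0))
  expect_equal(fit_efficiency(kd)$kcat_over_km, 1e5, tolerance = 1e-12)
  noisy <- make_synthetic_kinetics(fixture_spec(seed = 11, kinetics_slope = 146,
                                                kinetics_noise = 0.05,
                                                kinetics_n = 24))
  fe <- fit_efficiency(noisy)
  expect_lt(abs(fe$kcat_over_km - 146), 3 * fe$fit_error)
  zero <- kd
  zero$initial_rate <- 0
  expect_equal(fit_efficiency(zero)$kcat_over_km, 0)
  expect_error(fit_efficiency(kd[1, ]), "at least 2")
  same_s <- kd[c(1, 1), ]
  expect_error(fit_efficiency(same_s), "single substrate")
})

test_that("fit bias vanishes as noise goes to zero", {
  bias <- vapply(c(0.10, 0.02, 0.002), function(nz) {
    est <- vapply(1:20, function(s) {
      kd <- make_synthetic_kinetics(fixture_spec(seed = s, kinetics_slope = 500,
                                                 kinetics_noise = nz))
      fit_efficiency(kd)$kcat_over_km
    }, 0)
    abs(mean(est) - 500)
  }, 0)
  expect_true(all(diff(bias) < 0))
  expect_lt(bias[3], 0.5)
})

test_that("fold changes reproduce the printed efficiency ratios", {
  hg <- hg_series_mutations()
  eff <- setNames(hg$kcat_km, hg$variant)
  expect_equal(fold_change(eff[["HG4"]], eff[["HG3"]]), 705.4795,
               tolerance = 1e-4)
  expect_gte(fold_change(eff[["HG4"]], eff[["HG3"]]), 700)
  expect_equal(fold_change(eff[["HG3.3b"]], eff[["HG3"]]), 15.07,
               tolerance = 1e-3)
  expect_equal(fold_change(eff[["HG3"]], eff[["HG3"]]), 1)
  expect_error(fold_change(100, 0), "> 0")
})
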