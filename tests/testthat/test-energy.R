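ti <- list(r0 = 3.9, d0 = 0.10)
tj <- list(r0 = 3.5, d0 = 0.20)

test_that("Lennard-Jones term has its minimum at the 0.9-scaled radius", {
  r0ij <- toy_params$vdw_radius_scale * (ti$r0 + tj$r0) / 2
  d0ij <- sqrt(ti$d0 * tj$d0)
  expect_equal(lj_energy(ti, tj, r0ij, toy_params), -d0ij, tolerance = 1e-12)
  expect_lt(abs(lj_energy(ti, tj, 100 * r0ij, toy_params)), 1e-9)
  argmin <- golden_min(function(r) lj_energy(ti, tj, r, toy_params),
                       0.5 * r0ij, 2 * r0ij)
  expect_equal(argmin, r0ij, tolerance = 1e-6)
  expect_error(lj_energy(ti, tj, 0, toy_params), "r must be > 0")
})

test_that("LJ minimum location scales linearly with the radius scale", {
  slopes <- vapply(c(0.8, 0.9, 1.0, 1.1), function(s) {
    p <- energy_parameters(vdw_radius_scale = s)
    golden_min(function(r) lj_energy(ti, tj, r, p), 2, 6) / s
  }, 0)
  expect_lt(max(abs(slopes - (ti$r0 + tj$r0) / 2)), 1e-5)
})

test_that("hydrogen-bond well is -8 kcal/mol deep at 2.8 A under ideal angles", {
  d <- c(0, 0, 0)
  a <- c(2.8, 0, 0)
  expect_equal(hbond_energy(d, a, params = toy_params), -8.0, tolerance = 1e-12)
  # 90-degree donor-H-acceptor geometry kills the bond
  h <- c(0, 1, 0)  # D-H perpendicular to D...A
  expect_equal(hbond_energy(d, a, hydrogen = h, params = toy_params), 0)
  # linear D-H...A restores the ideal factor
  h2 <- c(1, 0, 0)
  expect_equal(hbond_energy(d, a, hydrogen = h2, params = toy_params), -8.0,
               tolerance = 1e-9)
  # argmin over R at ideal angles is the equilibrium distance
  argmin <- golden_min(function(r) hbond_energy(d, c(r, 0, 0), params = toy_params),
                       2.0, 4.0)
  expect_equal(argmin, 2.8, tolerance = 1e-6)
  # role violations are skipped, not errors
  expect_equal(hbond_energy(d, a, params = toy_params, donor_role = "none"), 0)
})

test_that("hydrogen-bond energy rises monotonically beyond the equilibrium", {
  rr <- seq(2.8, 6, by = 0.05)
  ee <- vapply(rr, function(r) hbond_energy(c(0, 0, 0), c(r, 0, 0),
                                            params = toy_params), 0)
  expect_true(all(diff(ee) > 0))
})

test_that("screened Coulomb term follows k q1 q2 / (10 r^2)", {
  expect_equal(coulomb_energy(1, 1, 1, toy_params), 33.20637, tolerance = 1e-9)
  expect_equal(coulomb_energy(0, 1, 2.5, toy_params), 0)
  expect_equal(coulomb_energy(0.4, -0.7, 3, toy_params),
               coulomb_energy(-0.7, 0.4, 3, toy_params))
  # log-log slope -2 with the distance-dependent dielectric
  r <- c(1, 2, 4, 8)
  e <- coulomb_energy(1, 1, r, toy_params)
  sl <- diff(log(e)) / diff(log(r))
  expect_lt(max(abs(sl + 2)), 1e-6)
  # constant-dielectric mode decays as 1/r
  pc <- energy_parameters(dielectric_mode = "constant")
  ec <- coulomb_energy(1, 1, r, pc)
  expect_lt(max(abs(diff(log(ec)) / diff(log(r)) + 1)), 1e-6)
  expect_error(coulomb_energy(1, 1, -1, toy_params), "r must be > 0")
})

test_that("solvation closed forms hold at zero and full occlusion", {
  expect_equal(solvation_energy(data.frame()[0, ], toy_params), 0)
  iso <- assign_atom_types(data.frame(name = "C1", element = "C",
                                      x = 0, y = 0, z = 0), toy_params)
  expect_equal(solvation_energy(iso, toy_params),
               toy_params$solv_nonpolar_exposure * toy_params$a_ref_default *
                 toy_params$solv_area_constant,
               tolerance = 1e-12)
  # dense cage saturates the occlusion estimator (f = 1)
  sh <- expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2), z = c(-2, 0, 2))
  sh <- sh[!(sh$x == 0 & sh$y == 0 & sh$z == 0), ]
  cage <- assign_atom_types(
    data.frame(name = c("O1", paste0("C", seq_len(nrow(sh)))),
               element = c("O", rep("C", nrow(sh))),
               x = c(0, sh$x), y = c(0, sh$y), z = c(0, sh$z)), toy_params)
  f_expect <- toy_params$solv_polar_burial * toy_params$a_ref_default *
    toy_params$solv_area_constant
  e_polar <- solvation_energy(cage[1, ], toy_params, occluders = cage)
  expect_lt(abs(e_polar - f_expect) / f_expect, 0.05)
  expect_error(solvation_energy(data.frame(name = "X", x = 0, y = 0, z = 0,
                                           polar = NA, a_ref = 1), toy_params),
               "missing typing")
})

test_that("secondary-structure classes and propensity lookups behave", {
  expect_equal(ss_class_from_dihedrals(-60, -45), "helix")
  expect_equal(ss_class_from_dihedrals(-120, 130), "strand")
  expect_equal(ss_class_from_dihedrals(60, 40), "other")
  expect_equal(ss_class_from_dihedrals(NA, -45), "other")
  p0 <- energy_parameters(ss_propensity_table = data.frame(
    res_type = character(0), ss_class = character(0), energy = numeric(0)))
  expect_equal(ss_propensity("ALA", "helix", p0), 0)
  p1 <- energy_parameters(ss_propensity_table = data.frame(
    res_type = "ALA", ss_class = "helix", energy = -0.5))
  expect_equal(ss_propensity("ALA", "helix", p1), -0.5)
  expect_equal(ss_propensity("ALA", "strand", p1), 0)
  expect_error(ss_propensity("XXX", "helix", p1, strict = TRUE), "unknown")
})

two_atom_model <- function(r, elements = c("C", "C"), resno = c(1L, 5L)) {
  atoms <- data.frame(record = "ATOM", serial = 1:2, name = c("C1", "C2"),
                      altloc = "", res_type = "UNK", chain = "A",
                      resno = resno, ins = "", x = c(0, r), y = 0, z = 0,
                      occ = 1, b = 0, element = elements, is_h = FALSE,
                      stringsAsFactors = FALSE)
  structure(list(model_id = 1L, source_tag = "single", atoms = atoms,
                 ligand = atoms[0, ], waters = atoms[0, ]),
            class = "structure_model")
}

test_that("total energy of a two-atom nonpolar system is the LJ term alone", {
  p <- energy_parameters(a_ref_default = 0)  # zero reference area: no solvation
  tc <- list(r0 = 3.898, d0 = 0.0951)
  r0ij <- 0.9 * 3.898
  bd <- total_energy(two_atom_model(r0ij), params = p)
  expect_equal(bd$vdw, -tc$d0, tolerance = 1e-9)
  expect_equal(bd$total, bd$vdw + bd$hbond + bd$coulomb + bd$solvation +
                 bd$ss_propensity + bd$geometry_bias, tolerance = 1e-12)
  expect_equal(bd$total, -tc$d0, tolerance = 1e-9)
})

test_that("atoms beyond the cutoff contribute only one-body terms", {
  m1 <- two_atom_model(5)
  bd1 <- total_energy(m1, params = toy_params)
  a3 <- m1$atoms[1, ]
  a3$name <- "C3"; a3$resno <- 50L; a3$x <- 50
  m2 <- m1; m2$atoms <- rbind(m1$atoms, a3)
  bd2 <- total_energy(m2, params = toy_params)
  expect_equal(bd2$vdw, bd1$vdw, tolerance = 1e-12)
  one_body_solv <- toy_params$solv_nonpolar_exposure *
    toy_params$a_ref_default * toy_params$solv_area_constant
  expect_equal(bd2$total - bd1$total, one_body_solv, tolerance = 1e-9)
})

test_that("pairwise decomposition matches a naive double-loop oracle", {
  set.seed(7)
  n <- 10
  xyz <- matrix(runif(3 * n, 0, 8), n, 3)
  q <- round(runif(n, -0.5, 0.5), 2)
  atoms <- data.frame(record = "ATOM", serial = seq_len(n),
                      name = paste0("C", seq_len(n)), altloc = "",
                      res_type = "UNK", chain = "A",
                      resno = seq(1L, by = 2L, length.out = n), ins = "",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = 0,
                      element = "C", is_h = FALSE, stringsAsFactors = FALSE)
  m <- structure(list(model_id = 1L, source_tag = "single", atoms = atoms,
                      ligand = atoms[0, ], waters = atoms[0, ]),
                 class = "structure_model")
  p <- energy_parameters(pair_cutoff = Inf)  # cutoff disabled for the oracle
  typ <- assign_atom_types(atoms, p)
  typ$charge <- q
  m$atoms$charge <- q
  # independent oracle: plain double loop over the documented formulas
  e_vdw <- 0; e_cou <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      r0 <- p$vdw_radius_scale * (typ$r0[i] + typ$r0[j]) / 2
      d0 <- sqrt(typ$d0[i] * typ$d0[j])
      e_vdw <- e_vdw + min(d0 * ((r0 / r)^12 - 2 * (r0 / r)^6), p$clash_ceiling)
      e_cou <- e_cou + p$coulomb_constant * q[i] * q[j] /
        (p$dielectric_coeff * r^2)
    }
  }
  w <- function(r) ifelse(r < p$occlusion_cutoff, (1 - r / p$occlusion_cutoff)^2, 0)
  e_sol <- 0
  for (i in seq_len(n)) {
    wt <- sum(w(sqrt(rowSums(sweep(xyz[-i, , drop = FALSE], 2, xyz[i, ])^2))))
    f <- min(1, wt / p$occlusion_saturation)
    e_sol <- e_sol + (-p$solv_nonpolar_burial * f +
                        p$solv_nonpolar_exposure * (1 - f)) *
      p$a_ref_default * p$solv_area_constant
  }
  bd <- total_energy(m, params = p)
  expect_equal(bd$vdw, e_vdw, tolerance = 1e-9)
  expect_equal(bd$coulomb, e_cou, tolerance = 1e-9)
  expect_equal(bd$solvation, e_sol, tolerance = 1e-9)
  expect_equal(bd$total, e_vdw + e_cou + e_sol, tolerance = 1e-9)
})

test_that("energies are invariant under global rotation and translation", {
  lib <- toy_pose_library()
  lig <- pose_ligand(toy_ligand, lib$poses[[1]])
  bd0 <- total_energy(toy_scaffold, lig, toy_params)
  R <- rot_z <- matrix(c(cos(0.7), sin(0.7), 0, -sin(0.7), cos(0.7), 0, 0, 0, 1), 3, 3)
  shift <- c(3, -2, 7)
  mv <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% R
    df$x <- xyz[, 1] + shift[1]; df$y <- xyz[, 2] + shift[2]
    df$z <- xyz[, 3] + shift[3]
    df
  }
  m2 <- toy_scaffold
  m2$atoms <- mv(m2$atoms)
  bd1 <- total_energy(m2, mv(lig), toy_params)
  for (term in c("vdw", "hbond", "coulomb", "solvation", "ss_propensity", "total"))
    expect_equal(bd1[[term]], bd0[[term]], tolerance = 1e-8, label = term)
})

test_that("clashing atoms are flagged and capped, not infinite", {
  m <- two_atom_model(0.005)
  bd <- total_energy(m, params = toy_params)
  expect_true(bd$clash)
  expect_true(is.finite(bd$total))
  expect_lte(bd$vdw, toy_params$clash_ceiling)
})
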