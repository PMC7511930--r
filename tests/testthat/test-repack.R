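toy_design <- design_spec(data.frame(chain = "A", resno = c(5, 9, 13),
                                     res_type = c("LEU", "SER", "VAL")))

toy_matrix <- function(design = toy_design, poses = NULL, specs = NULL) {
  build_energy_matrix(toy_scaffold, poses, design, toy_rotlib, toy_params,
                      ligand = if (!is.null(poses)) toy_ligand,
                      specs = specs)
}

test_that("matrix shapes follow the design spec", {
  d1 <- design_spec(data.frame(chain = "A", resno = 5, res_type = "SER"))
  m1 <- toy_matrix(d1)
  expect_length(m1$one_body, 1L)
  expect_length(m1$two_body, 0L)
  expect_equal(m1$n_choices, 9L)  # 3 records x 3 chi1 expansions
  d2 <- design_spec(data.frame(chain = "A", resno = c(5, 9),
                               res_type = c("ALA", "SER")))
  m2 <- toy_matrix(d2)
  expect_equal(m2$n_choices, c(1L, 9L))
  expect_length(m2$two_body, 1L)
  expect_equal(dim(m2$two_body[[1]]$mat), c(1L, 9L))
})

test_that("two-body terms are symmetric under pair swap", {
  m <- toy_matrix()
  for (tb in m$two_body) {
    A <- m$choices[[tb$i]][[2]]$atoms
    B <- m$choices[[tb$j]][[2]]$atoms
    expect_equal(ensrepack:::pair_sum(A, B, toy_params),
                 ensrepack:::pair_sum(B, A, toy_params), tolerance = 1e-12)
  }
})

test_that("positions without rotamers are rejected", {
  empty_lib <- load_rotamer_library(
    "res_type\tprob\tchi1\tchi2\tchi3\tchi4\tsd1\tsd2\tsd3\tsd4\nVAL\t1\t175\t\t\t\t8\t\t\t")
  d <- design_spec(data.frame(chain = "A", resno = 5, res_type = "SER"))
  expect_error(build_energy_matrix(toy_scaffold, NULL, d, empty_lib, toy_params),
               "zero available rotamers")
})

test_that("matrix-summed energies equal direct structure energies", {
  lib <- toy_pose_library(dof_grids = list(distance = c(2.7, 2.8, 2.9)))
  m <- toy_matrix(poses = lib$poses, specs = list(toy_contact))
  set.seed(99)
  for (t in 1:20) {
    asg <- vapply(m$n_choices, function(n) sample.int(n, 1L), 0L)
    me <- matrix_energy(m, asg)
    mat <- materialize_assignment(m, asg)
    te <- total_energy(mat$model, mat$ligand, toy_params,
                       context = list(background = m$bgatoms,
                                      specs = list(toy_contact)))
    expect_equal(me, te$total, tolerance = 1e-6)
  }
})

test_that("brute force enumerates a hand-checkable 2x2 problem", {
  m <- random_matrix(c(2L, 2L), seed = 1)
  m$one_body <- list(c(1, 0), c(2, -1))
  m$two_body[[1]]$mat <- matrix(c(0, 5, -3, 1), 2, 2)
  # energies: (1,1)=3, (2,1)=7, (1,2)=-3, (2,2)=0 -> min at (1,2)
  bf <- brute_force(m)
  expect_equal(unname(bf$assignment), c(1L, 2L))
  expect_equal(bf$energy, -3)
  m1 <- random_matrix(1L, seed = 1)
  expect_equal(unname(brute_force(m1)$assignment), 1L)
})

test_that("brute force breaks ties lexicographically and guards size", {
  m <- random_matrix(c(3L, 3L), seed = 2)
  m$one_body <- list(rep(0, 3), rep(0, 3))
  m$two_body[[1]]$mat <- matrix(0, 3, 3)
  expect_equal(unname(brute_force(m)$assignment), c(1L, 1L))
  big <- random_matrix(rep(11L, 6L), seed = 3)
  expect_error(brute_force(big), "guard")
})

test_that("annealing finds dominant minima and is seed-deterministic", {
  m <- random_matrix(c(4L, 4L), seed = 5, scale = 1)
  # carve a unique minimum separated by >= 50 kcal/mol
  m$one_body[[1]][2] <- -100
  m$one_body[[2]][3] <- -100
  for (s in c(1, 99, 12345)) {
    r <- anneal(m, annealing_schedule(seed = s))
    expect_equal(unname(r$assignment), c(2L, 3L))
  }
  r1 <- anneal(m, annealing_schedule(seed = 42))
  r2 <- anneal(m, annealing_schedule(seed = 42))
  expect_identical(r1$assignment, r2$assignment)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace) <= 1e-12))  # best-so-far never increases
})

test_that("annealing matches the exhaustive oracle on 625-combination problems", {
  hits <- 0L
  for (s in 1:20) {
    m <- random_matrix(c(5L, 5L, 5L, 5L), seed = 100 + s)
    bf <- brute_force(m)
    an <- anneal(m, annealing_schedule(seed = s))
    expect_gte(an$energy, bf$energy - 1e-9)
    if (abs(an$energy - bf$energy) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("repack_sequence composes placement, annealing and references", {
  lib <- toy_pose_library(dof_grids = list(distance = c(2.7, 2.8, 2.9)))
  d <- design_spec(data.frame(chain = "A", resno = c(5, 9),
                              res_type = c("LEU", "SER")))
  sch <- annealing_schedule(seed = 11)
  rr <- repack_sequence(toy_scaffold, toy_ligand, select_lowest(lib, 1), d,
                        toy_rotlib, toy_params, sch, specs = list(toy_contact))
  # composition: single pose run equals anneal on the corresponding matrix
  m <- build_energy_matrix(toy_scaffold, select_lowest(lib, 1)$poses, d,
                           toy_rotlib, toy_params, ligand = toy_ligand,
                           specs = list(toy_contact))
  an <- anneal(m, sch)
  expect_equal(rr$energy, an$energy, tolerance = 1e-9)
  expect_identical(unname(rr$assignment), unname(an$assignment))
  # breakdown recomputed from the assignment matches the matrix energy
  expect_equal(rr$breakdown$total, matrix_energy(m, rr$assignment),
               tolerance = 1e-6)
})

test_that("the best starting pose is recorded in the provenance", {
  lib <- toy_pose_library(dof_grids = list(distance = c(2.7, 2.8, 2.9)))
  d <- design_spec(data.frame(chain = "A", resno = 5, res_type = "SER"))
  rr <- repack_sequence(toy_scaffold, toy_ligand, lib, d, toy_rotlib,
                        toy_params, annealing_schedule(seed = 2),
                        specs = list(toy_contact))
  # recompute each pose's matrix optimum to identify the true best start
  energies <- vapply(seq_along(lib$poses), function(k) {
    m <- build_energy_matrix(toy_scaffold, list(lib$poses[[k]]), d, toy_rotlib,
                             toy_params, ligand = toy_ligand,
                             specs = list(toy_contact))
    brute_force(m)$energy
  }, 0)
  expect_equal(rr$pose_index, which.min(energies))
  expect_equal(rr$provenance$starting_pose_id,
               lib$poses[[which.min(energies)]]$id)
})

test_that("an all-Gly design repacked against itself has zero delta", {
  lib <- toy_pose_library()
  d <- design_spec(data.frame(chain = "A", resno = c(5, 9),
                              res_type = c("GLY", "GLY")))
  rr <- repack_sequence(toy_scaffold, toy_ligand, lib, d, toy_rotlib,
                        toy_params, annealing_schedule(seed = 1),
                        specs = list(toy_contact))
  expect_equal(rr$delta_vs_allgly, 0, tolerance = 1e-9)
})

test_that("energy_delta is a checked difference of totals", {
  bd1 <- ensrepack:::new_energy_breakdown(-30, 0, 0, -20, 0, 0,
                                          fingerprint = "x")
  bd2 <- ensrepack:::new_energy_breakdown(-20, 0, 0, -10, 0, 0,
                                          fingerprint = "x")
  expect_equal(energy_delta(bd1, bd2), -20)
  expect_equal(energy_delta(bd1, bd1), 0)
  bd3 <- ensrepack:::new_energy_breakdown(-20, 0, 0, -10, 0, 0,
                                          fingerprint = "y")
  expect_error(energy_delta(bd1, bd3), "mismatch")
})

test_that("a constructed LJ-minimum contact shifts the delta by its depth", {
  # two-atom system: repacking replaces nothing but adds one contact at the
  # LJ minimum of depth d0; the delta against the all-Gly reference equals
  # the one-body term of the added atom
  m <- random_matrix(1L, seed = 1)
  d0 <- 0.5
  m$one_body <- list(c(-d0))
  m$constant <- -10
  bf <- brute_force(m)
  expect_equal(bf$energy - m$constant, -d0, tolerance = 1e-6)
})
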