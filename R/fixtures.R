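# Synthetic fixtures: every test input is generated in code (toy pocket
# scaffolds, a planar toy ligand, a generic rotamer library, synthetic
# B-factor profiles and kinetics), so tests document their own provenance
# and nothing is downloaded. The toy ligand is deliberately generic
# chemistry: no parameterization of any real transition state is claimed.

#' Fixture generation parameters
#'
#' @param seed integer seed recorded in every fixture's provenance and used
#'   for all stochastic fields.
#' @param scaffold_size residue count of the toy scaffold (>= 8).
#' @param pocket_radius guaranteed heavy-atom clearance around the pocket
#'   centroid, Angstrom.
#' @param bfactor_baseline mean B of the non-loop residues, A^2.
#' @param bfactor_loop_inflation multiplicative B inflation of the loop
#'   residues (1 = no contrast).
#' @param bfactor_noise_sd Gaussian noise on B, A^2.
#' @param kinetics_slope true kcat/KM, 1/(M s).
#' @param kinetics_noise fractional rate noise (sd as a fraction of each
#'   rate).
#' @param kinetics_n number of kinetic points.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, scaffold_size = 16L, pocket_radius = 6,
                         bfactor_baseline = 20, bfactor_loop_inflation = 1,
                         bfactor_noise_sd = 0, kinetics_slope = 146,
                         kinetics_noise = 0, kinetics_n = 24L) {
  stopifnot(scaffold_size >= 8L, pocket_radius > 0, bfactor_baseline > 0,
            bfactor_loop_inflation > 0, bfactor_noise_sd >= 0,
            kinetics_slope >= 0, kinetics_noise >= 0)
  structure(list(seed = as.integer(seed), scaffold_size = as.integer(scaffold_size),
                 pocket_radius = pocket_radius,
                 bfactor_baseline = bfactor_baseline,
                 bfactor_loop_inflation = bfactor_loop_inflation,
                 bfactor_noise_sd = bfactor_noise_sd,
                 kinetics_slope = kinetics_slope,
                 kinetics_noise = kinetics_noise,
                 kinetics_n = as.integer(kinetics_n)),
            class = "fixture_spec")
}

#' Toy pocket scaffold
#'
#' A poly-Ala ring: residues arranged on a circle of radius
#' `pocket_radius + 3.2` around the origin with a small vertical wave, beta
#' carbons tilted toward the pocket. Every heavy atom stays farther than
#' `pocket_radius` from the pocket centroid (the origin), and the model
#' passes structure validation and PDB round-tripping. Deterministic per
#' spec (bit-reproducible).
#'
#' @param spec a [fixture_spec()].
#' @param chain chain identifier.
#' @return a `structure_model`.
#' @export
make_toy_scaffold <- function(spec = fixture_spec(), chain = "A") {
  n <- spec$scaffold_size
  R <- spec$pocket_radius + 3.2
  rows <- list()
  for (i in seq_len(n)) {
    th <- 2 * pi * (i - 1) / n
    rh <- c(cos(th), sin(th), 0)       # radial (outward)
    tg <- c(-sin(th), cos(th), 0)      # tangential
    zz <- c(0, 0, 1)
    zlev <- 0.9 * if (i %% 2 == 0) 1 else -1
    ca <- R * rh + zlev * zz
    # N behind and C ahead of CA along the chain direction, both lifted off
    # the CA plane (same side, so N-CA-C is bent and dihedrals are defined)
    nn <- ca - 0.78 * tg + c(0, 0, 0.52)
    cc <- ca + 0.78 * tg + c(0, 0, 0.52)
    oo <- cc + 1.23 * rh
    cb <- ca - 1.53 * (cos(deg2rad(35)) * rh) + 1.53 * sin(deg2rad(35)) * zz
    at <- function(nm, el, p) data.frame(
      record = "ATOM", serial = NA_integer_, name = nm, altloc = "",
      res_type = "ALA", chain = chain, resno = i, ins = "",
      x = p[1], y = p[2], z = p[3], occ = 1, b = spec$bfactor_baseline,
      element = el, is_h = FALSE, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- rbind(at("N", "N", nn), at("CA", "C", ca),
                                       at("C", "C", cc), at("O", "O", oo),
                                       at("CB", "C", cb))
  }
  new_structure_model(do.call(rbind, rows), model_id = spec$seed,
                      source_tag = "single")
}

#' Toy planar ligand
#'
#' A fixed 9-atom planar ligand (six-membered ring plus three exocyclic
#' atoms) carrying one hydrogen-bond donor nitrogen and one acceptor oxygen
#' so contact specs are exercisable. Charges sum to -1 and the geometric
#' center sits at the origin in the z = 0 plane.
#'
#' @return ligand atom table with `name`, `element`, coordinates, `charge`,
#'   `polar`, `role` columns.
#' @export
make_toy_ligand <- function() {
  ring_names <- c("C1", "C2", "C3", "C4", "C5", "N6")
  ring_el <- c("C", "C", "C", "C", "C", "N")
  th <- deg2rad(seq(0, 300, by = 60))
  xy <- cbind(1.39 * cos(th), 1.39 * sin(th))
  exo <- rbind(c(2.75, 0), 2.75 * c(cos(deg2rad(120)), sin(deg2rad(120))),
               2.75 * c(cos(deg2rad(180)), sin(deg2rad(180))))
  lig <- data.frame(
    name = c(ring_names, "O7", "C8", "C9"),
    element = c(ring_el, "O", "C", "C"),
    x = c(xy[, 1], exo[, 1]), y = c(xy[, 2], exo[, 2]), z = 0,
    charge = 0, polar = FALSE, role = "none",
    is_h = FALSE, stringsAsFactors = FALSE)
  lig$charge[lig$name == "O7"] <- -0.55
  lig$charge[lig$name == "N6"] <- -0.45
  lig$polar[lig$name %in% c("O7", "N6")] <- TRUE
  lig$role[lig$name == "N6"] <- "donor"
  lig$role[lig$name == "O7"] <- "acceptor"
  ctr <- c(mean(lig$x), mean(lig$y), mean(lig$z))
  lig$x <- lig$x - ctr[1]; lig$y <- lig$y - ctr[2]; lig$z <- lig$z - ctr[3]
  lig
}

#' Toy backbone-independent rotamer library
#'
#' A small generic library in the documented TSV dialect covering every
#' standard side-chain type (so any point mutation target is buildable),
#' with 2-3 rotamers per type and nonzero standard deviations on chi1/chi2.
#'
#' @return a `rotamer_library`.
#' @export
make_toy_rotamer_library <- function() {
  row <- function(rt, prob, chi, sds) {
    chi <- c(chi, rep(NA, 4 - length(chi)))
    sds <- c(sds, rep(NA, 4 - length(sds)))
    paste(c(rt, prob, chi, sds), collapse = "\t")
  }
  lines <- c(
    "res_type\tprob\tchi1\tchi2\tchi3\tchi4\tsd1\tsd2\tsd3\tsd4",
    row("SER", 0.45, -65, 9), row("SER", 0.35, 180, 10), row("SER", 0.20, 62, 9),
    row("CYS", 0.55, -65, 9), row("CYS", 0.45, 180, 10),
    row("VAL", 0.60, 175, 8), row("VAL", 0.30, -60, 8), row("VAL", 0.10, 62, 9),
    row("THR", 0.50, -61, 8), row("THR", 0.43, 62, 8), row("THR", 0.07, 180, 10),
    row("ILE", 0.60, c(-61, 169), c(8, 10)), row("ILE", 0.25, c(-59, -64), c(8, 10)),
    row("LEU", 0.60, c(-65, 175), c(8, 9)), row("LEU", 0.30, c(-172, 62), c(9, 10)),
    row("ASP", 0.55, c(-68, -15), c(9, 14)), row("ASP", 0.45, c(-177, 4), c(10, 14)),
    row("ASN", 0.50, c(-68, -35), c(9, 20)), row("ASN", 0.50, c(-177, 30), c(10, 20)),
    row("GLU", 0.55, c(-67, 180, -10), c(9, 12, 15)),
    row("GLU", 0.45, c(-177, 70, 10), c(10, 12, 15)),
    row("GLN", 0.40, c(-67, 180, -20), c(9, 12, 15)),
    row("GLN", 0.35, c(-177, 65, 20), c(10, 12, 15)),
    row("GLN", 0.25, c(-65, -65, -40), c(9, 12, 15)),
    row("LYS", 0.55, c(-67, 180, 180, 180), c(9, 12, 12, 12)),
    row("LYS", 0.45, c(-177, 68, 180, 65), c(10, 12, 12, 12)),
    row("ARG", 0.55, c(-67, 180, 180, 180), c(9, 12, 12, 12)),
    row("ARG", 0.45, c(-177, 65, 180, -85), c(10, 12, 12, 12)),
    row("MET", 0.55, c(-65, 180, 75), c(9, 12, 14)),
    row("MET", 0.45, c(-178, 65, -75), c(10, 12, 14)),
    row("PHE", 0.60, c(-66, 94), c(9, 15)), row("PHE", 0.40, c(177, 80), c(10, 15)),
    row("TYR", 0.60, c(-66, 94), c(9, 15)), row("TYR", 0.40, c(177, 80), c(10, 15)),
    row("TRP", 0.55, c(-67, 100), c(9, 15)), row("TRP", 0.45, c(-177, -105), c(10, 15)),
    row("HIS", 0.55, c(-63, -75), c(9, 15)), row("HIS", 0.45, c(-177, 65), c(10, 15)),
    row("PRO", 0.60, c(28, -35), c(6, 6)), row("PRO", 0.40, c(-28, 35), c(6, 6))
  )
  load_rotamer_library(lines)
}

#' Synthetic B-factor profile with a rigidified/flexible loop
#'
#' Assigns `B = baseline * inflation^loop + noise` so a designated loop
#' carries a multiplicatively inflated mean B relative to the rest of the
#' scaffold, giving Z-score analyses a known ground truth (inflation 1 means
#' no contrast).
#'
#' @param model a `structure_model`.
#' @param spec a [fixture_spec()] (baseline, inflation, noise sd, seed).
#' @param loop_resno residue numbers forming the loop; default the middle
#'   quarter of the model's residues.
#' @return the model with B-factors replaced.
#' @export
make_synthetic_bfactors <- function(model, spec = fixture_spec(),
                                    loop_resno = NULL) {
  a <- model$atoms
  resnos <- sort(unique(a$resno))
  if (is.null(loop_resno)) {
    nq <- max(2L, length(resnos) %/% 4L)
    st <- (length(resnos) - nq) %/% 2L + 1L
    loop_resno <- resnos[seq(st, st + nq - 1L)]
  }
  set.seed(spec$seed)
  in_loop <- a$resno %in% loop_resno
  b <- spec$bfactor_baseline * ifelse(in_loop, spec$bfactor_loop_inflation, 1)
  if (spec$bfactor_noise_sd > 0)
    b <- b + rnorm(length(b), sd = spec$bfactor_noise_sd)
  a$b <- pmax(b, 0.01)
  model$atoms <- a
  attr(model, "loop_resno") <- loop_resno
  model
}

#' Synthetic steady-state kinetics in the linear regime
#'
#' Sub-saturating substrate grid with
#' `v0 = slope * [E0] * [S] * (1 + eps)`, `eps ~ N(0, noise^2)`, seeded.
#'
#' @param spec a [fixture_spec()] (slope, noise fraction, n points, seed).
#' @param enzyme_conc enzyme concentration, M.
#' @param s_max top of the substrate grid, M (kept below saturation).
#' @return data frame of class `kinetics_data` with columns
#'   `substrate_conc`, `initial_rate`, `enzyme_conc`.
#' @export
make_synthetic_kinetics <- function(spec = fixture_spec(), enzyme_conc = 2e-6,
                                    s_max = 1e-3) {
  n <- spec$kinetics_n
  if (n < 1L) stop("empty substrate grid")
  s <- seq(s_max / n, s_max, length.out = n)
  set.seed(spec$seed)
  eps <- if (spec$kinetics_noise > 0) rnorm(n, sd = spec$kinetics_noise) else 0
  v0 <- spec$kinetics_slope * enzyme_conc * s * (1 + eps)
  out <- data.frame(substrate_conc = s, initial_rate = v0,
                    enzyme_conc = enzyme_conc)
  class(out) <- c("kinetics_data", "data.frame")
  attr(out, "true_slope") <- spec$kinetics_slope
  attr(out, "seed") <- spec$seed
  out
}
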