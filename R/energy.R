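# Pairwise-decomposable scoring function for design: Lennard-Jones 12-6
# (Dreiding-style combining rules, radii scaled by 0.9), a directional 12-10
# hydrogen-bond term, screened Coulomb electrostatics with a
# distance-dependent dielectric, an occlusion-based solvation potential, a
# secondary-structure propensity term, and an additive contact-geometry bias.

#' Scoring-function parameters
#'
#' All energies are kcal/mol, distances Angstrom, charges elementary units.
#'
#' @param vdw_radius_scale multiplier on combined vdW equilibrium radii.
#' @param hb_well_depth hydrogen-bond well depth (positive magnitude).
#' @param hb_r0 equilibrium donor-acceptor heavy-atom distance.
#' @param dielectric_coeff dielectric coefficient; with
#'   `dielectric_mode = "distance-dependent"` the effective dielectric is
#'   `coeff * r`, i.e. energies fall off as 1/r^2.
#' @param dielectric_mode `"distance-dependent"` (default) or `"constant"`.
#' @param solv_nonpolar_burial,solv_nonpolar_exposure,solv_polar_burial
#'   solvation scale factors.
#' @param solv_area_constant area-to-energy constant, kcal/mol/A^2, applied
#'   to every solvation term.
#' @param a_ref_default reference exposure area per heavy atom, A^2.
#' @param occlusion_cutoff,occlusion_saturation occlusion estimator: each
#'   neighbour within the cutoff contributes `(1 - r/cutoff)^2`; the sum is
#'   divided by the saturation constant and clamped to \[0, 1\].
#' @param coulomb_constant kcal A / (mol e^2).
#' @param pair_cutoff hard cutoff for all pair terms (no switching); set to
#'   `Inf` to disable.
#' @param hbond_max_dist donor-acceptor distance beyond which hydrogen bonds
#'   are not evaluated.
#' @param clash_distance pair distance flagged as an atomic clash.
#' @param clash_ceiling per-pair energy cap keeping Monte Carlo numerics
#'   finite.
#' @param ss_propensity_table data frame (`res_type`, `ss_class`, `energy`).
#' @param geometry_bias_default bonus (kcal/mol, <= 0) granted to a satisfied
#'   contact-geometry spec that does not set its own.
#' @return object of class `energy_parameters`.
#' @export
energy_parameters <- function(vdw_radius_scale = 0.9,
                              hb_well_depth = 8.0,
                              hb_r0 = 2.8,
                              dielectric_coeff = 10,
                              dielectric_mode = c("distance-dependent", "constant"),
                              solv_nonpolar_burial = 0.05,
                              solv_nonpolar_exposure = 2.5,
                              solv_polar_burial = 1.0,
                              solv_area_constant = 0.02,
                              a_ref_default = 25,
                              occlusion_cutoff = 5.0,
                              occlusion_saturation = 3.0,
                              coulomb_constant = 332.0637,
                              pair_cutoff = 12,
                              hbond_max_dist = 5.0,
                              clash_distance = 0.01,
                              clash_ceiling = 1000,
                              ss_propensity_table = default_ss_table(),
                              geometry_bias_default = -100) {
  dielectric_mode <- match.arg(dielectric_mode)
  p <- list(vdw_radius_scale = vdw_radius_scale, hb_well_depth = hb_well_depth,
            hb_r0 = hb_r0, dielectric_coeff = dielectric_coeff,
            dielectric_mode = dielectric_mode,
            solv_nonpolar_burial = solv_nonpolar_burial,
            solv_nonpolar_exposure = solv_nonpolar_exposure,
            solv_polar_burial = solv_polar_burial,
            solv_area_constant = solv_area_constant,
            a_ref_default = a_ref_default,
            occlusion_cutoff = occlusion_cutoff,
            occlusion_saturation = occlusion_saturation,
            coulomb_constant = coulomb_constant, pair_cutoff = pair_cutoff,
            hbond_max_dist = hbond_max_dist, clash_distance = clash_distance,
            clash_ceiling = clash_ceiling,
            ss_propensity_table = ss_propensity_table,
            geometry_bias_default = geometry_bias_default)
  stopifnot(vdw_radius_scale >= 0, hb_well_depth >= 0, hb_r0 > 0,
            dielectric_coeff > 0, solv_area_constant >= 0)
  structure(p, class = "energy_parameters")
}

params_fingerprint <- function(params) {
  tab <- params$ss_propensity_table
  paste(c(unlist(params[setdiff(names(params), "ss_propensity_table")]),
          if (!is.null(tab)) paste(tab$res_type, tab$ss_class, tab$energy)),
        collapse = ";")
}

#' Default secondary-structure propensity table (kcal/mol)
#' @return data frame with columns `res_type`, `ss_class`, `energy`.
#' @export
default_ss_table <- function() {
  data.frame(
    res_type = c("ALA", "LEU", "GLN", "GLU", "MET", "LYS", "GLY", "PRO",
                 "VAL", "ILE", "PHE", "TYR", "THR", "TRP"),
    ss_class = c(rep("helix", 8), rep("strand", 6)),
    energy = c(-0.30, -0.25, -0.20, -0.30, -0.20, -0.15, 0.50, 1.00,
               -0.30, -0.30, -0.20, -0.20, -0.15, -0.20),
    stringsAsFactors = FALSE
  )
}

# Dreiding-like per-element vdW parameters: r0 = equilibrium diameter (A),
# d0 = well depth (kcal/mol).
ELEMENT_TYPES <- data.frame(
  element = c("C", "N", "O", "S", "H", "P", "X"),
  r0 = c(3.898, 3.662, 3.405, 4.030, 3.195, 4.15, 3.50),
  d0 = c(0.0951, 0.0774, 0.0957, 0.3440, 0.0152, 0.32, 0.05),
  polar = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
  role = c("none", "donor", "acceptor", "none", "none", "none", "none"),
  stringsAsFactors = FALSE
)

#' Assign force-field typings to an atom table
#'
#' Fills `r0`, `d0`, `polar`, `role`, `charge` and `a_ref` columns from a
#' per-element table with name-based overrides (hydroxyl oxygens act as both
#' donor and acceptor; backbone nitrogens donate, carbonyl oxygens accept).
#' Existing columns are kept, so ligand tables may carry their own charges
#' and roles.
#'
#' @param atoms data frame with at least `name` and `element` columns.
#' @param params [energy_parameters()].
#' @return the atom table with typing columns added.
#' @export
assign_atom_types <- function(atoms, params = energy_parameters()) {
  i <- match(atoms$element, ELEMENT_TYPES$element)
  i[is.na(i)] <- nrow(ELEMENT_TYPES)
  if (is.null(atoms$r0)) atoms$r0 <- ELEMENT_TYPES$r0[i]
  if (is.null(atoms$d0)) atoms$d0 <- ELEMENT_TYPES$d0[i]
  if (is.null(atoms$polar)) atoms$polar <- ELEMENT_TYPES$polar[i]
  if (is.null(atoms$role)) {
    role <- ELEMENT_TYPES$role[i]
    role[atoms$name %in% c("OG", "OG1", "OH")] <- "both"
    atoms$role <- role
  }
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$a_ref))
    atoms$a_ref <- ifelse(atoms$element == "H", 0, params$a_ref_default)
  atoms
}

#' Lennard-Jones 12-6 pair energy
#'
#' `E = D0ij * ((R0ij/r)^12 - 2 (R0ij/r)^6)` with
#' `R0ij = vdw_radius_scale * (r0_i + r0_j)/2` (arithmetic mean) and
#' `D0ij = sqrt(d0_i * d0_j)` (geometric mean).
#'
#' @param typing_i,typing_j lists or 1-row data frames with `r0`, `d0`.
#' @param r separation(s), Angstrom, > 0.
#' @param params [energy_parameters()].
#' @return energy, kcal/mol (vectorised over `r`).
#' @export
lj_energy <- function(typing_i, typing_j, r, params = energy_parameters()) {
  if (any(r <= 0)) stop("lj_energy: r must be > 0")
  r0 <- params$vdw_radius_scale * (typing_i$r0 + typing_j$r0) / 2
  d0 <- sqrt(typing_i$d0 * typing_j$d0)
  s6 <- (r0 / r)^6
  d0 * (s6^2 - 2 * s6)
}

hb_angular_factor <- function(donor, acceptor, hydrogen = NULL,
                              acceptor_base = NULL, ideal_base_angle = 120) {
  f1 <- 1
  if (!is.null(hydrogen)) {
    th <- bond_angle(donor, hydrogen, acceptor)
    f1 <- if (th <= 90) 0 else cos(deg2rad(180 - th))^2
  }
  f2 <- 1
  if (!is.null(acceptor_base)) {
    phi <- bond_angle(acceptor_base, acceptor, donor)
    dev <- abs(phi - ideal_base_angle)
    f2 <- if (dev >= 90) 0 else cos(deg2rad(dev))^2
  }
  f1 * f2
}

#' Directional hydrogen-bond energy
#'
#' Hybrid 12-10 radial form scaled by an angular factor:
#' `E = well_depth * (5 (r0/R)^12 - 6 (r0/R)^10) * F(theta, phi)`, where `R`
#' is the donor-acceptor heavy-atom distance. `F` is 1 at ideal geometry
#' (linear donor-H-acceptor, hybridization-appropriate approach angle at the
#' acceptor) and 0 when the donor-H-acceptor angle collapses to 90 degrees,
#' so the minimum is exactly `-well_depth` at `R = r0`.
#'
#' @param donor,acceptor length-3 coordinates of the heavy atoms. If roles
#'   are supplied via `donor_role`/`acceptor_role` and violated, the
#'   contribution is zero (skipped, not an error).
#' @param hydrogen optional donor hydrogen coordinates; omitted, the
#'   donor-H-acceptor factor is taken at its ideal value of 1.
#' @param acceptor_base optional acceptor bonded-neighbour coordinates used
#'   for the approach-angle factor.
#' @param params [energy_parameters()].
#' @param ideal_base_angle ideal approach angle at the acceptor, degrees
#'   (120 for sp2, 109.5 for sp3).
#' @param donor_role,acceptor_role optional role labels checked against
#'   `"donor"`/`"acceptor"`/`"both"`.
#' @return energy, kcal/mol.
#' @export
hbond_energy <- function(donor, acceptor, hydrogen = NULL, acceptor_base = NULL,
                         params = energy_parameters(), ideal_base_angle = 120,
                         donor_role = NULL, acceptor_role = NULL) {
  if (!is.null(donor_role) && !donor_role %in% c("donor", "both")) return(0)
  if (!is.null(acceptor_role) && !acceptor_role %in% c("acceptor", "both")) return(0)
  R <- vnorm(acceptor - donor)
  if (R <= 0) stop("hbond_energy: coincident donor and acceptor")
  f <- hb_angular_factor(donor, acceptor, hydrogen, acceptor_base, ideal_base_angle)
  x <- params$hb_r0 / R
  params$hb_well_depth * (5 * x^12 - 6 * x^10) * f
}

#' Screened Coulomb pair energy
#'
#' With the default distance-dependent dielectric `eps(r) = coeff * r`, the
#' energy is `k q_i q_j / (coeff * r^2)`.
#'
#' @param q_i,q_j charges, elementary units.
#' @param r separation(s), Angstrom, > 0.
#' @param params [energy_parameters()].
#' @return energy, kcal/mol (vectorised over `r`).
#' @export
coulomb_energy <- function(q_i, q_j, r, params = energy_parameters()) {
  if (any(r <= 0)) stop("coulomb_energy: r must be > 0")
  denom <- if (params$dielectric_mode == "distance-dependent")
    params$dielectric_coeff * r^2 else params$dielectric_coeff * r
  params$coulomb_constant * q_i * q_j / denom
}

# Occlusion fraction in [0, 1] of each atom in `atoms` against `occluders`.
# Neighbour weight (1 - r/cutoff)^2 within the cutoff; the accumulated
# weight is divided by the saturation constant and clamped. Self pairs
# (matching uid, or the diagonal when occluders are the atoms themselves)
# are excluded.
occlusion_fraction <- function(atoms, params, occluders = NULL) {
  self <- is.null(occluders)
  if (self) occluders <- atoms
  n <- nrow(atoms)
  if (n == 0L) return(numeric(0))
  ax <- as.matrix(atoms[, c("x", "y", "z")])
  ox <- as.matrix(occluders[, c("x", "y", "z")])
  f <- numeric(n)
  cut <- params$occlusion_cutoff
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(ox) - ax[i, ])^2))
    skip <- if (self) seq_len(nrow(ox)) == i
            else if (!is.null(atoms$uid) && !is.null(occluders$uid))
              occluders$uid == atoms$uid[i]
            else d < 1e-9
    w <- (1 - d / cut)^2
    w[d >= cut | skip] <- 0
    f[i] <- min(1, sum(w) / params$occlusion_saturation)
  }
  f
}

#' Occlusion-based solvation energy
#'
#' For each heavy atom an occlusion fraction `f` in \[0, 1\] is accumulated
#' from pairwise proximity within a cutoff. Nonpolar atoms contribute
#' `-s_np_burial * f * A_ref * c + s_np_exposure * (1 - f) * A_ref * c`;
#' polar atoms contribute `s_polar_burial * f * A_ref * c`, with `c` the
#' area-to-energy constant.
#'
#' @param atoms typed atom table (see [assign_atom_types()]); an error names
#'   the first atom lacking a typing.
#' @param params [energy_parameters()].
#' @param occluders optional typed atom table used as the occluding
#'   environment instead of `atoms` itself (frozen-background mode).
#' @return total solvation energy, kcal/mol.
#' @export
solvation_energy <- function(atoms, params = energy_parameters(), occluders = NULL) {
  if (nrow(atoms) == 0L) return(0)
  if (is.null(atoms$polar) || is.null(atoms$a_ref) || anyNA(atoms$polar))
    stop("solvation_energy: missing typing for atom ",
         atoms$name[which(is.na(atoms$polar))[1L]])
  f <- occlusion_fraction(atoms, params, occluders)
  c0 <- params$solv_area_constant
  e_np <- -params$solv_nonpolar_burial * f * atoms$a_ref * c0 +
    params$solv_nonpolar_exposure * (1 - f) * atoms$a_ref * c0
  e_p <- params$solv_polar_burial * f * atoms$a_ref * c0
  sum(ifelse(atoms$polar, e_p, e_np))
}

#' Secondary-structure class from backbone dihedrals
#'
#' Fixed phi/psi boxes: helix for phi in \[-100, -30\] and psi in
#' \[-80, -5\]; strand for phi in \[-180, -45\] with psi in \[90, 180\] or
#' \[-180, -150\]; everything else (including chain termini with undefined
#' dihedrals) is `"other"`.
#'
#' @param phi,psi backbone dihedrals, degrees (NA allowed).
#' @return `"helix"`, `"strand"` or `"other"`.
#' @export
ss_class_from_dihedrals <- function(phi, psi) {
  cls <- rep("other", length(phi))
  ok <- !is.na(phi) & !is.na(psi)
  cls[ok & phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5] <- "helix"
  st <- ok & phi >= -180 & phi <= -45 & ((psi >= 90 & psi <= 180) | (psi >= -180 & psi <= -150))
  cls[st & cls == "other"] <- "strand"
  cls
}

#' Secondary-structure propensity lookup
#'
#' @param res_type 3-letter code.
#' @param ss_class `"helix"`, `"strand"` or `"other"`.
#' @param params [energy_parameters()] carrying the propensity table.
#' @param strict error on residue types absent from the standard set.
#' @return table energy, kcal/mol; zero when the table omits the pair.
#' @export
ss_propensity <- function(res_type, ss_class, params = energy_parameters(),
                          strict = FALSE) {
  if (strict && !toupper(res_type) %in% names(N_CHI))
    stop("unknown residue type ", res_type)
  tab <- params$ss_propensity_table
  if (is.null(tab) || nrow(tab) == 0L) return(0)
  i <- which(tab$res_type == toupper(res_type) & tab$ss_class == ss_class)
  if (length(i) == 0L) return(0)
  tab$energy[i[1L]]
}

# ---- assembled-system scoring ------------------------------------------

# Typed protein atom table with uid, residue key, backbone flag, hydrogen-
# bond acceptor base coordinates (nearest heavy atom of the same residue)
# and secondary-structure class columns.
typed_protein_atoms <- function(model, params) {
  a <- assign_atom_types(model$atoms, params)
  a$uid <- paste(a$chain, a$resno, a$ins, a$name, sep = "|")
  a$resid <- paste(a$chain, a$resno, a$ins, sep = "|")
  a$is_bb <- a$name %in% BACKBONE_ATOMS
  add_acceptor_base(a)
}

add_acceptor_base <- function(a) {
  a$bx <- NA_real_; a$by <- NA_real_; a$bz <- NA_real_
  acc <- which(a$role %in% c("acceptor", "both"))
  for (i in acc) {
    sameres <- which(a$resid == a$resid[i] & !a$is_h & seq_len(nrow(a)) != i)
    if (length(sameres) == 0L) next
    d <- sqrt((a$x[sameres] - a$x[i])^2 + (a$y[sameres] - a$y[i])^2 +
              (a$z[sameres] - a$z[i])^2)
    j <- sameres[which.min(d)]
    a$bx[i] <- a$x[j]; a$by[i] <- a$y[j]; a$bz[i] <- a$z[j]
  }
  a
}

typed_ligand_atoms <- function(ligand, params) {
  l <- assign_atom_types(ligand, params)
  l$uid <- paste0("LIG|", l$name)
  l$resid <- "LIG"
  l$is_bb <- FALSE
  l$chain <- "_L"; l$resno <- 0L; l$ins <- ""
  if (is.null(l$is_h)) l$is_h <- l$element == "H"
  add_acceptor_base(l)
}

# Pairwise vdW + Coulomb + H-bond between atom sets A and B (cross terms
# only), honouring the hard cutoff, same-residue exclusion, the
# adjacent-residue backbone exclusion and the clash ceiling.
pair_terms <- function(A, B, params) {
  out <- list(vdw = 0, coulomb = 0, hbond = 0, clash = FALSE)
  if (nrow(A) == 0L || nrow(B) == 0L) return(out)
  ax <- as.matrix(A[, c("x", "y", "z")])
  bx <- as.matrix(B[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(bx^2)) - 2 * ax %*% t(bx)
  d <- sqrt(pmax(d2, 0))
  excl <- outer(A$resid, B$resid, "==")
  adj <- outer(A$is_bb, B$is_bb, "&") &
    outer(paste(A$chain, A$ins), paste(B$chain, B$ins), "==") &
    abs(outer(A$resno, B$resno, "-")) == 1
  adj[is.na(adj)] <- FALSE
  use <- !excl & !adj & d <= params$pair_cutoff
  if (!any(use)) return(out)
  clash <- use & d < params$clash_distance
  out$clash <- any(clash)
  d_safe <- pmax(d, params$clash_distance / 2)
  # vdW
  r0 <- params$vdw_radius_scale * outer(A$r0, B$r0, "+") / 2
  d0 <- sqrt(outer(A$d0, B$d0))
  s6 <- (r0 / d_safe)^6
  evdw <- pmin(d0 * (s6^2 - 2 * s6), params$clash_ceiling)
  out$vdw <- sum(evdw[use])
  # Coulomb
  qq <- outer(A$charge, B$charge)
  cz <- use & qq != 0
  if (any(cz)) {
    denom <- if (params$dielectric_mode == "distance-dependent")
      params$dielectric_coeff * d_safe^2 else params$dielectric_coeff * d_safe
    ec <- pmin(params$coulomb_constant * qq / denom, params$clash_ceiling)
    out$coulomb <- sum(ec[cz])
  }
  # hydrogen bonds (both donor->acceptor directions), ideal donor-H factor
  hb <- 0
  hb_pairs <- which(use & d <= params$hbond_max_dist, arr.ind = TRUE)
  if (nrow(hb_pairs) > 0L) {
    for (k in seq_len(nrow(hb_pairs))) {
      i <- hb_pairs[k, 1L]; j <- hb_pairs[k, 2L]
      hb <- hb + hb_pair_energy(A, i, B, j, params)
      hb <- hb + hb_pair_energy(B, j, A, i, params)
    }
  }
  out$hbond <- hb
  out
}

hb_pair_energy <- function(D, i, Acc, j, params) {
  if (!D$role[i] %in% c("donor", "both")) return(0)
  if (!Acc$role[j] %in% c("acceptor", "both")) return(0)
  base <- if (!is.na(Acc$bx[j])) c(Acc$bx[j], Acc$by[j], Acc$bz[j]) else NULL
  hbond_energy(c(D$x[i], D$y[i], D$z[i]), c(Acc$x[j], Acc$y[j], Acc$z[j]),
               hydrogen = NULL, acceptor_base = base, params = params)
}

# Backbone phi/psi and ss class per residue of a structure_model.
residue_ss_classes <- function(model) {
  a <- model$atoms
  keys <- residue_keys(model)
  get <- function(key, nm) {
    p <- strsplit(key, "|", fixed = TRUE)[[1L]]
    if (length(p) < 3L) p <- c(p, rep("", 3L - length(p)))
    i <- which(a$chain == p[1L] & a$resno == as.integer(p[2L]) &
               a$ins == p[3L] & a$name == nm)
    if (length(i) == 0L) return(NULL)
    c(a$x[i[1L]], a$y[i[1L]], a$z[i[1L]])
  }
  res_ch <- vapply(strsplit(keys, "|", fixed = TRUE), `[`, "", 1L)
  res_no <- as.integer(vapply(strsplit(keys, "|", fixed = TRUE), `[`, "", 2L))
  cls <- character(length(keys))
  for (k in seq_along(keys)) {
    n <- get(keys[k], "N"); ca <- get(keys[k], "CA"); c0 <- get(keys[k], "C")
    prev <- which(res_ch == res_ch[k] & res_no == res_no[k] - 1L)
    nxt <- which(res_ch == res_ch[k] & res_no == res_no[k] + 1L)
    phi <- psi <- NA_real_
    if (length(prev) == 1L && !is.null(n) && !is.null(ca) && !is.null(c0)) {
      cp <- get(keys[prev], "C")
      if (!is.null(cp)) phi <- dihedral_angle(cp, n, ca, c0)
    }
    if (length(nxt) == 1L && !is.null(n) && !is.null(ca) && !is.null(c0)) {
      nn <- get(keys[nxt], "N")
      if (!is.null(nn)) psi <- dihedral_angle(n, ca, c0, nn)
    }
    cls[k] <- ss_class_from_dihedrals(phi, psi)
  }
  names(cls) <- keys
  cls
}

residue_types_by_key <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resno, a$ins, sep = "|")
  tapply(a$res_type, key, `[`, 1L)[residue_keys(model)]
}

#' Total energy of a structure (optionally with a ligand pose)
#'
#' Sums pairwise Lennard-Jones, hydrogen-bond and Coulomb terms over all
#' atom pairs within the hard cutoff (intra-residue and peptide-adjacent
#' backbone pairs excluded), per-atom occlusion solvation, per-residue
#' secondary-structure propensity, and the contact-geometry bias for every
#' satisfied spec. Atom pairs closer than the clash distance set the clash
#' flag and per-pair energies are capped at the documented ceiling.
#'
#' @param model a `structure_model`.
#' @param ligand optional ligand atom table (columns `name`, `element`,
#'   `x`, `y`, `z`, plus optional typing columns) — e.g. `model$ligand`, a
#'   [make_toy_ligand()] or a posed ligand from [pose_ligand()].
#' @param params [energy_parameters()].
#' @param context optional design context: `list(background = <typed atom
#'   table>)` freezes the solvation occluder environment to that background
#'   (used by the repacker so the interaction matrix decomposes exactly), and
#'   `specs = list(<contact_spec>)` enables the geometry bias.
#' @return an `energy_breakdown` with components `vdw`, `hbond`, `coulomb`,
#'   `solvation`, `ss_propensity`, `geometry_bias` and their sum `total`.
#' @export
total_energy <- function(model, ligand = NULL, params = energy_parameters(),
                         context = NULL) {
  prot <- typed_protein_atoms(model, params)
  lig <- if (!is.null(ligand) && nrow(ligand) > 0L)
    typed_ligand_atoms(ligand, params) else NULL
  cols <- c("name", "element", "x", "y", "z", "charge", "r0", "d0", "polar",
            "role", "a_ref", "uid", "resid", "is_bb", "is_h", "bx", "by", "bz")
  all_atoms <- prot[, intersect(cols, names(prot))]
  all_atoms$chain <- prot$chain; all_atoms$resno <- prot$resno; all_atoms$ins <- prot$ins
  if (!is.null(lig)) {
    lg <- lig[, intersect(cols, names(lig))]
    lg$chain <- "_L"; lg$resno <- 0L; lg$ins <- ""
    all_atoms <- rbind(all_atoms[, sort(names(all_atoms))], lg[, sort(names(lg))])
  }
  # pair terms via an upper-triangular sweep over residues would be
  # quadratic anyway at these sizes; do one full pass with double-count halving
  pt <- pair_terms(all_atoms, all_atoms, params)
  vdw <- pt$vdw / 2; coul <- pt$coulomb / 2; hbond <- pt$hbond / 2
  clash <- pt$clash
  # solvation (heavy atoms)
  heavy <- all_atoms[!all_atoms$is_h, , drop = FALSE]
  occl <- if (!is.null(context$background)) context$background else NULL
  solv <- solvation_energy(heavy, params, occluders = occl)
  # propensity
  cls <- residue_ss_classes(model)
  rty <- residue_types_by_key(model)
  ssp <- sum(vapply(seq_along(cls),
                    function(k) ss_propensity(rty[[k]], cls[[k]], params), 0))
  # geometry bias
  bias <- 0
  if (!is.null(context$specs) && !is.null(lig)) {
    for (sp in context$specs) {
      gs <- geometry_check(model, lig, sp)
      if (gs$satisfied) bias <- bias + spec_bias(sp, params)
    }
  }
  new_energy_breakdown(vdw, hbond, coul, solv, ssp, bias, clash,
                       params_fingerprint(params))
}

new_energy_breakdown <- function(vdw, hbond, coulomb, solvation, ssp, bias,
                                 clash = FALSE, fingerprint = "") {
  total <- vdw + hbond + coulomb + solvation + ssp + bias
  structure(list(vdw = vdw, hbond = hbond, coulomb = coulomb,
                 solvation = solvation, ss_propensity = ssp,
                 geometry_bias = bias, total = total, clash = clash,
                 params_fingerprint = fingerprint),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown> kcal/mol\n")
  for (nm in c("vdw", "hbond", "coulomb", "solvation", "ss_propensity",
               "geometry_bias", "total"))
    cat(sprintf("  %-14s %10.4f\n", nm, x[[nm]]))
  if (isTRUE(x$clash)) cat("  ** atomic clash flagged **\n")
  invisible(x)
}
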