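# Targeted transition-state placement: ligand poses are constructed by
# internal-coordinate building from a protein anchor frame over discretized
# contact degrees of freedom (distance, angles, dihedrals), clash-filtered,
# scored with the pairwise energy model plus the contact-geometry bias, and
# optionally expanded over a rigid-body perturbation grid.

#' Catalytic contact-geometry specification
#'
#' Describes an idealized catalytic contact between ordered protein anchor
#' atoms and ligand anchor atoms. The last protein anchor is the contact
#' atom; the first ligand anchor is the ligand contact atom. Geometry DOFs
#' measured against the spec, with `pB`, `pC` the last two protein anchors
#' and `L1`, `L2`, `L3` the ligand anchors:
#' distance `pC-L1`; angles `pB-pC-L1` and `pC-L1-L2`; dihedrals
#' `pA-pB-pC-L1`, `pB-pC-L1-L2` and `pC-L1-L2-L3`.
#'
#' @param protein_anchors character vector of at least three atom references
#'   `"chain/resno/atom"`, ordered with the contact atom last.
#' @param ligand_anchors at least three ligand atom names, contact atom
#'   first.
#' @param distance `c(target, tolerance)` in Angstrom.
#' @param angles list of `c(target, tolerance)` in degrees (up to 2).
#' @param dihedrals list of `c(target, tolerance)` in degrees (up to 3).
#' @param bias bonus (kcal/mol, <= 0) added when the spec is satisfied;
#'   `NULL` uses `geometry_bias_default` from the energy parameters.
#' @return object of class `contact_spec`.
#' @export
contact_spec <- function(protein_anchors, ligand_anchors,
                         distance = c(2.8, 0.4),
                         angles = list(c(120, 20)),
                         dihedrals = list(),
                         bias = NULL) {
  stopifnot(length(protein_anchors) >= 3L, length(ligand_anchors) >= 3L,
            length(distance) == 2L, distance[2L] > 0)
  for (a in angles) stopifnot(length(a) == 2L, a[2L] > 0)
  for (a in dihedrals) stopifnot(length(a) == 2L, a[2L] > 0)
  if (!is.null(bias) && bias > 0) stop("bias must be a bonus (<= 0)")
  structure(list(protein_anchors = protein_anchors,
                 ligand_anchors = ligand_anchors,
                 distance = distance, angles = angles, dihedrals = dihedrals,
                 bias = bias),
            class = "contact_spec")
}

spec_bias <- function(spec, params) {
  if (!is.null(spec$bias)) spec$bias else params$geometry_bias_default
}

anchor_coords <- function(model, refs) {
  t(vapply(refs, function(r) {
    i <- resolve_atom_ref(model, r)
    c(model$atoms$x[i], model$atoms$y[i], model$atoms$z[i])
  }, numeric(3)))
}

ligand_anchor_coords <- function(lig, names) {
  i <- match(names, lig$name)
  if (anyNA(i)) stop("unresolvable ligand anchor atom(s): ",
                     paste(names[is.na(i)], collapse = ", "))
  cbind(lig$x[i], lig$y[i], lig$z[i])
}

# Measure the contact DOFs of a ligand placement against a spec.
geometry_check <- function(model, lig, spec) {
  p <- anchor_coords(model, spec$protein_anchors)
  np <- nrow(p)
  pA <- p[np - 2L, ]; pB <- p[np - 1L, ]; pC <- p[np, ]
  l <- ligand_anchor_coords(lig, spec$ligand_anchors)
  dev <- list()
  d <- vnorm(l[1L, ] - pC)
  dev$distance <- d - spec$distance[1L]
  ok <- abs(dev$distance) <= spec$distance[2L]
  meas_ang <- c(bond_angle(pB, pC, l[1L, ]), bond_angle(pC, l[1L, ], l[2L, ]))
  if (length(spec$angles) > 0L) {
    dev$angles <- numeric(length(spec$angles))
    for (k in seq_along(spec$angles)) {
      dev$angles[k] <- meas_ang[k] - spec$angles[[k]][1L]
      ok <- ok && abs(dev$angles[k]) <= spec$angles[[k]][2L]
    }
  }
  meas_dih <- c(dihedral_angle(pA, pB, pC, l[1L, ]),
                dihedral_angle(pB, pC, l[1L, ], l[2L, ]),
                dihedral_angle(pC, l[1L, ], l[2L, ], l[3L, ]))
  if (length(spec$dihedrals) > 0L) {
    dev$dihedrals <- numeric(length(spec$dihedrals))
    for (k in seq_along(spec$dihedrals)) {
      dev$dihedrals[k] <- wrap_angle(meas_dih[k] - spec$dihedrals[[k]][1L])
      ok <- ok && abs(dev$dihedrals[k]) <= spec$dihedrals[[k]][2L]
    }
  }
  list(satisfied = ok, deviations = dev,
       measured = list(distance = d, angles = meas_ang, dihedrals = meas_dih))
}

new_ts_pose <- function(coords, id = 1L, translation = c(0, 0, 0),
                        rotation = c(0, 0, 0), score = NA_real_,
                        satisfied = list(), dof = NULL) {
  structure(list(id = id, translation = translation, rotation = rotation,
                 coords = coords, score = score, satisfied = satisfied,
                 dof = dof),
            class = "ts_pose")
}

new_pose_library <- function(poses, provenance = list()) {
  structure(list(poses = poses, provenance = provenance),
            class = "pose_library")
}

#' @export
print.pose_library <- function(x, ...) {
  sc <- vapply(x$poses, function(p) p$score, 0)
  cat(sprintf("<pose_library> %d poses; score range [%.3f, %.3f]\n",
              length(x$poses), suppressWarnings(min(sc)), suppressWarnings(max(sc))))
  invisible(x)
}

#' @export
length.pose_library <- function(x) length(x$poses)

#' Apply a pose to a ligand atom table
#'
#' @param ligand ligand atom table (base coordinates).
#' @param pose a `ts_pose`.
#' @return the ligand table with coordinates replaced by the pose coordinates.
#' @export
pose_ligand <- function(ligand, pose) {
  stopifnot(nrow(ligand) == nrow(pose$coords))
  ligand$x <- pose$coords[, 1L]
  ligand$y <- pose$coords[, 2L]
  ligand$z <- pose$coords[, 3L]
  ligand
}

ligand_coord_matrix <- function(lig) as.matrix(lig[, c("x", "y", "z")])

#' Generate transition-state poses by targeted ligand placement
#'
#' Ligand poses are built from the protein anchor frame of the first spec
#' over the discretized contact DOFs, clash-filtered against the protein
#' heavy atoms (anchor-atom pairs exempt), then scored as the
#' protein-ligand interaction energy with the bias of every satisfied spec
#' added. The returned library is sorted ascending by score (stable in
#' enumeration order).
#'
#' @param template a `structure_model`.
#' @param ligand ligand atom table with typing columns (see
#'   [make_toy_ligand()]).
#' @param specs list of [contact_spec()]; the first defines the build frame.
#' @param dof_grids named list of DOF value grids overriding the spec
#'   targets: `distance`, `angle`, `dihedral` (contact frame),
#'   `angle2`, `dihedral2`, `dihedral3` (ligand orientation). Defaults are
#'   the spec targets with `dihedral = 180`, `angle2 = 120`,
#'   `dihedral2 = 180`, `dihedral3 = 0` when unspecified.
#' @param params [energy_parameters()].
#' @param clash_threshold heavy-atom protein-ligand distance below which a
#'   pose is discarded, Angstrom.
#' @return a `pose_library`; empty (with a warning) when no pose survives.
#' @export
generate_poses <- function(template, ligand, specs, dof_grids = NULL,
                           params = energy_parameters(), clash_threshold = 2.0) {
  stopifnot(length(specs) >= 1L)
  sp <- specs[[1L]]
  p <- anchor_coords(template, sp$protein_anchors)
  np <- nrow(p)
  pA <- p[np - 2L, ]; pB <- p[np - 1L, ]; pC <- p[np, ]
  lbase <- ligand_anchor_coords(ligand, sp$ligand_anchors)
  grid_of <- function(nm, default) {
    if (!is.null(dof_grids[[nm]])) dof_grids[[nm]] else default
  }
  g <- list(
    distance  = grid_of("distance", sp$distance[1L]),
    angle     = grid_of("angle", if (length(sp$angles) >= 1L) sp$angles[[1L]][1L] else 120),
    dihedral  = grid_of("dihedral", if (length(sp$dihedrals) >= 1L) sp$dihedrals[[1L]][1L] else 180),
    angle2    = grid_of("angle2", if (length(sp$angles) >= 2L) sp$angles[[2L]][1L] else 120),
    dihedral2 = grid_of("dihedral2", if (length(sp$dihedrals) >= 2L) sp$dihedrals[[2L]][1L] else 180),
    dihedral3 = grid_of("dihedral3", if (length(sp$dihedrals) >= 3L) sp$dihedrals[[3L]][1L] else 0)
  )
  if (any(vapply(g, length, 0L) == 0L)) stop("empty DOF grid")
  combos <- expand.grid(g, KEEP.OUT.ATTRS = FALSE)
  base_xyz <- ligand_coord_matrix(ligand)
  prot <- typed_protein_atoms(template, params)
  prot_heavy <- prot[!prot$is_h, , drop = FALSE]
  anchor_uid <- vapply(sp$protein_anchors, function(r) {
    i <- resolve_atom_ref(template, r)
    paste(template$atoms$chain[i], template$atoms$resno[i],
          template$atoms$ins[i], template$atoms$name[i], sep = "|")
  }, "")
  l12 <- vnorm(lbase[2L, ] - lbase[1L, ])
  l23 <- vnorm(lbase[3L, ] - lbase[2L, ])
  a123 <- bond_angle(lbase[1L, ], lbase[2L, ], lbase[3L, ])
  poses <- list()
  for (k in seq_len(nrow(combos))) {
    co <- combos[k, ]
    L1 <- place_atom(pA, pB, pC, co$distance, co$angle, co$dihedral)
    L2 <- place_atom(pB, pC, L1, l12, co$angle2, co$dihedral2)
    L3 <- place_atom(pC, L1, L2, l23, a123, co$dihedral3)
    tr <- kabsch(lbase, rbind(L1, L2, L3))
    coords <- apply_transform(base_xyz, tr)
    lp <- ligand
    lp$x <- coords[, 1L]; lp$y <- coords[, 2L]; lp$z <- coords[, 3L]
    # clash filter (heavy atoms; anchor pairs exempt)
    heavy_l <- which(lp$element != "H")
    clash <- FALSE
    for (j in heavy_l) {
      d <- sqrt((prot_heavy$x - lp$x[j])^2 + (prot_heavy$y - lp$y[j])^2 +
                (prot_heavy$z - lp$z[j])^2)
      exempt <- prot_heavy$uid %in% anchor_uid & lp$name[j] %in% sp$ligand_anchors
      if (any(d < clash_threshold & !exempt)) { clash <- TRUE; break }
    }
    if (clash) next
    ltyped <- typed_ligand_atoms(lp, params)
    pt <- pair_terms(ltyped, prot, params)
    score <- pt$vdw + pt$coulomb + pt$hbond
    sat <- lapply(specs, function(s) geometry_check(template, lp, s))
    for (si in seq_along(specs))
      if (sat[[si]]$satisfied) score <- score + spec_bias(specs[[si]], params)
    poses[[length(poses) + 1L]] <-
      new_ts_pose(coords, id = k, score = score, satisfied = sat,
                  dof = as.list(co))
  }
  if (length(poses) == 0L)
    warning("no poses survived the clash filter: empty pose library")
  ord <- order(vapply(poses, function(p) p$score, 0))
  new_pose_library(poses[ord],
                   provenance = list(template_id = template$model_id,
                                     n_specs = length(specs),
                                     clash_threshold = clash_threshold))
}

#' Rigid-body perturbation grid around a pose
#'
#' Enumerates the full Cartesian product of translations
#' `{-range, ..., 0, ..., +range}` along x, y, z and rotations about the
#' three axes applied about the pose geometric center (rotation composition
#' fixed as Rz Ry Rx). The identity pose is always included; with the
#' defaults the grid holds 5 values per axis over 6 axes, i.e. 15,625 poses.
#'
#' @param pose a `ts_pose`.
#' @param trans_range,trans_step translation range and step, Angstrom.
#' @param rot_range,rot_step rotation range and step, degrees.
#' @return a `pose_library` of perturbed poses (unscored).
#' @export
perturb_pose_grid <- function(pose, trans_range = 0.4, trans_step = 0.2,
                              rot_range = 10, rot_step = 5) {
  axis_values <- function(range, step, what) {
    if (range < 0 || step <= 0) stop(what, ": range must be >= 0 and step > 0")
    if (range == 0) return(0)
    k <- range / step
    if (abs(k - round(k)) > 1e-9)
      stop(what, ": range must be an integer multiple of step")
    seq(-range, range, by = step)
  }
  tv <- axis_values(trans_range, trans_step, "translation")
  rv <- axis_values(rot_range, rot_step, "rotation")
  combos <- expand.grid(tx = tv, ty = tv, tz = tv, rx = rv, ry = rv, rz = rv,
                        KEEP.OUT.ATTRS = FALSE)
  ctr <- colMeans(pose$coords)
  centered <- sweep(pose$coords, 2, ctr)
  poses <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    co <- combos[k, ]
    if (all(co == 0)) {
      coords <- pose$coords
    } else {
      R <- rot_z(co$rz) %*% rot_y(co$ry) %*% rot_x(co$rx)
      coords <- sweep(centered %*% t(R), 2, ctr + c(co$tx, co$ty, co$tz), "+")
    }
    poses[[k]] <- new_ts_pose(coords, id = k,
                              translation = c(co$tx, co$ty, co$tz),
                              rotation = c(co$rx, co$ry, co$rz),
                              score = pose$score, satisfied = pose$satisfied,
                              dof = pose$dof)
  }
  new_pose_library(poses, provenance = list(parent_id = pose$id,
                                            trans_range = trans_range,
                                            trans_step = trans_step,
                                            rot_range = rot_range,
                                            rot_step = rot_step))
}

#' Check a pose against a contact-geometry spec
#'
#' @param pose a `ts_pose`.
#' @param spec a [contact_spec()].
#' @param template the `structure_model` holding the protein anchors.
#' @param ligand the ligand atom table the pose coordinates belong to.
#' @return list with `satisfied` (logical) and signed `deviations`.
#' @export
geometry_satisfied <- function(pose, spec, template, ligand) {
  geometry_check(template, pose_ligand(ligand, pose), spec)
}

#' Lowest-scoring poses of a library
#'
#' @param library a `pose_library` (sorted ascending by score).
#' @param n number of poses to keep; if `n` exceeds the library size all
#'   poses are returned with a warning.
#' @return a `pose_library` with the first `n` poses; score ties keep
#'   enumeration order (deterministic).
#' @export
select_lowest <- function(library, n = 1L) {
  stopifnot(n >= 1L)
  poses <- library$poses
  if (n > length(poses)) {
    warning("n exceeds library size; returning all ", length(poses), " poses")
    n <- length(poses)
  }
  sc <- vapply(poses, function(p) p$score, 0)
  ord <- order(sc)  # stable: ties keep input order
  new_pose_library(poses[ord[seq_len(n)]], provenance = library$provenance)
}
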