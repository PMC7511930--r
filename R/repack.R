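# Combinatorial side-chain / transition-state optimization. The repacking
# problem is decomposed into an interaction matrix (one-body terms against
# the fixed all-Gly background plus two-body terms between designable
# positions, with the TS pose set treated as one super-position), then
# searched by Metropolis Monte Carlo with geometric simulated annealing (a
# compiled core with a portable xoshiro256++ PRNG) or solved exactly by
# exhaustive enumeration for oracle-sized problems.

#' Design specification for repacking
#'
#' @param positions data frame with columns `chain`, `resno` (and optional
#'   `ins`) and `res_type` — the designable positions and their (fixed)
#'   target amino acids; every position samples all rotamers of that type.
#' @param catalytic optional subset of position keys flagged as catalytic
#'   (identity fixed, conformations sampled — which is true of every
#'   position here; the flag is bookkeeping).
#' @param ts_as_position treat the transition-state pose set as one
#'   super-position searched jointly with the rotamers (default); `FALSE`
#'   repacks against each fixed pose separately (nested mode).
#' @param expansion chi [expansion_policy()] applied to library records.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(positions, catalytic = character(0),
                        ts_as_position = TRUE,
                        expansion = expansion_policy()) {
  stopifnot(is.data.frame(positions),
            all(c("chain", "resno", "res_type") %in% names(positions)))
  if (is.null(positions$ins)) positions$ins <- ""
  positions$res_type <- toupper(positions$res_type)
  key <- paste(positions$chain, positions$resno, positions$ins, sep = "|")
  if (anyDuplicated(key)) stop("design positions must be unique")
  bad <- !positions$res_type %in% names(N_CHI)
  if (any(bad)) stop("unknown target amino acid(s): ",
                     paste(unique(positions$res_type[bad]), collapse = ", "))
  structure(list(positions = positions, keys = key, catalytic = catalytic,
                 ts_as_position = ts_as_position, expansion = expansion),
            class = "design_spec")
}

# Template with the design positions stripped to backbone and re-typed.
strip_design_positions <- function(template, design, types = NULL) {
  a <- template$atoms
  for (k in seq_len(nrow(design$positions))) {
    p <- design$positions[k, ]
    sel <- a$chain == p$chain & a$resno == p$resno & a$ins == p$ins
    if (!any(sel)) stop("design position ", design$keys[k], " missing from template")
    a$res_type[sel] <- if (is.null(types)) p$res_type else types
    drop <- sel & !(a$name %in% BACKBONE_ATOMS)
    a <- a[!drop, , drop = FALSE]
  }
  template$atoms <- a
  template
}

pair_sum <- function(A, B, params) {
  pt <- pair_terms(A, B, params)
  pt$vdw + pt$coulomb + pt$hbond
}

make_choice_atoms <- function(bb, sc, chain, resno, ins, res_type, params) {
  res <- data.frame(
    name = c(bb$name, sc$name), element = c(bb$element, sc$element),
    x = c(bb$x, sc$x), y = c(bb$y, sc$y), z = c(bb$z, sc$z),
    stringsAsFactors = FALSE)
  res$chain <- chain; res$resno <- resno; res$ins <- ins
  res$res_type <- res_type
  res$is_h <- res$element == "H"
  res <- assign_atom_types(res, params)
  res$uid <- paste(chain, resno, ins, res$name, sep = "|")
  res$resid <- paste(chain, resno, ins, sep = "|")
  res$is_bb <- res$name %in% BACKBONE_ATOMS
  res <- add_acceptor_base(res)
  res[!res$is_bb, , drop = FALSE]
}

position_choices <- function(template, p, library, expansion, params) {
  bb <- residue_atoms(template, p$chain, p$resno, p$ins)
  bb <- bb[bb$name %in% c("N", "CA", "C", "O") & !bb$is_h, , drop = FALSE]
  if (p$res_type == "GLY") {
    sc <- build_side_chain(bb, "GLY")
    return(list(list(chi = numeric(0),
                     atoms = make_choice_atoms(bb, sc, p$chain, p$resno, p$ins,
                                               "GLY", params))))
  }
  if (p$res_type == "ALA") {
    sc <- build_side_chain(bb, "ALA")
    return(list(list(chi = numeric(0),
                     atoms = make_choice_atoms(bb, sc, p$chain, p$resno, p$ins,
                                               "ALA", params))))
  }
  recs <- library_records(library, p$res_type)
  if (nrow(recs) == 0L)
    stop("position ", paste(p$chain, p$resno, sep = "/"),
         ": zero available rotamers for ", p$res_type)
  out <- list()
  for (r in seq_len(nrow(recs))) {
    variants <- expand_rotamer(recs[r, , drop = FALSE], expansion)
    for (v in seq_len(nrow(variants))) {
      chi <- record_chi(variants[v, , drop = FALSE])
      sc <- build_side_chain(bb, p$res_type, chi)
      out[[length(out) + 1L]] <-
        list(chi = chi, atoms = make_choice_atoms(bb, sc, p$chain, p$resno,
                                                  p$ins, p$res_type, params))
    }
  }
  out
}

# Which design position (index) a spec's protein anchors touch; 0L = all
# anchors live on the fixed background.
spec_anchor_position <- function(spec, design) {
  hits <- integer(0)
  for (ref in spec$protein_anchors) {
    parts <- strsplit(ref, "/", fixed = TRUE)[[1L]]
    key <- if (length(parts) == 3L) paste(parts[1L], parts[2L], "", sep = "|")
           else paste(parts[1L], parts[2L], parts[3L], sep = "|")
    i <- match(key, design$keys)
    if (!is.na(i)) hits <- c(hits, i)
  }
  hits <- unique(hits)
  if (length(hits) > 1L)
    stop("a contact spec may reference at most one designable position")
  if (length(hits) == 0L) 0L else hits
}

augment_model <- function(bg_model, choice_atoms) {
  if (nrow(choice_atoms) == 0L) return(bg_model)
  a <- bg_model$atoms
  add <- data.frame(record = "ATOM", serial = NA_integer_,
                    name = choice_atoms$name, altloc = "",
                    res_type = choice_atoms$res_type,
                    chain = choice_atoms$chain, resno = choice_atoms$resno,
                    ins = choice_atoms$ins, x = choice_atoms$x,
                    y = choice_atoms$y, z = choice_atoms$z,
                    occ = 1, b = 0, element = choice_atoms$element,
                    is_h = choice_atoms$is_h, stringsAsFactors = FALSE)
  bg_model$atoms <- rbind(a[, names(add)], add)
  bg_model
}

#' Build the repacking interaction matrix
#'
#' One-body energies hold each choice's interaction with the fixed all-Gly
#' background (pair terms plus frozen-background occlusion solvation, plus
#' contact-geometry bias for specs anchored entirely on the background);
#' two-body energies hold choice-choice pair terms, including TS-side-chain
#' terms with the bias applied where the spec anchors a designable position.
#' The matrix energy of any assignment equals [total_energy()] of the
#' materialized structure under the same frozen-background context.
#'
#' @param template a `structure_model`.
#' @param pose_set list of `ts_pose` (or a `pose_library`) forming the TS
#'   super-position; `NULL` for pure side-chain repacking.
#' @param design a [design_spec()].
#' @param library a `rotamer_library`.
#' @param params [energy_parameters()].
#' @param ligand ligand atom table the poses refer to (required with
#'   `pose_set`).
#' @param specs optional list of [contact_spec()] for the geometry bias.
#' @return an `interaction_matrix`.
#' @export
build_energy_matrix <- function(template, pose_set = NULL, design, library,
                                params = energy_parameters(), ligand = NULL,
                                specs = NULL) {
  if (inherits(pose_set, "pose_library")) pose_set <- pose_set$poses
  if (!is.null(pose_set) && length(pose_set) == 0L)
    stop("pose_set is empty")
  if (!is.null(pose_set) && is.null(ligand))
    stop("ligand table required with a pose set")
  bg_model <- strip_design_positions(template, design)
  bgatoms <- typed_protein_atoms(bg_model, params)
  npos <- nrow(design$positions)
  choices <- vector("list", npos)
  for (k in seq_len(npos))
    choices[[k]] <- position_choices(template, design$positions[k, ], library,
                                     design$expansion, params)
  labels <- design$keys
  spec_pos <- if (is.null(specs)) integer(0)
              else vapply(specs, spec_anchor_position, 0L, design = design)
  has_ts <- !is.null(pose_set)
  ts_idx <- if (has_ts) npos + 1L else 0L
  ts_atoms <- NULL
  if (has_ts) {
    ts_atoms <- lapply(pose_set, function(p)
      typed_ligand_atoms(pose_ligand(ligand, p), params))
    labels <- c(labels, "TS")
  }
  n_choices <- c(vapply(choices, length, 0L),
                 if (has_ts) length(pose_set))
  # one-body
  one_body <- vector("list", length(labels))
  for (k in seq_len(npos)) {
    one_body[[k]] <- vapply(choices[[k]], function(ch) {
      if (nrow(ch$atoms) == 0L) return(0)
      pair_sum(ch$atoms, bgatoms, params) +
        solvation_energy(ch$atoms[!ch$atoms$is_h, , drop = FALSE], params,
                         occluders = bgatoms)
    }, 0)
  }
  if (has_ts) {
    one_body[[ts_idx]] <- vapply(seq_along(ts_atoms), function(ci) {
      la <- ts_atoms[[ci]]
      e <- pair_sum(la, bgatoms, params) +
        solvation_energy(la[!la$is_h, , drop = FALSE], params,
                         occluders = bgatoms)
      if (!is.null(specs)) {
        for (si in which(spec_pos == 0L)) {
          gs <- geometry_check(bg_model, pose_ligand(ligand, pose_set[[ci]]),
                               specs[[si]])
          if (gs$satisfied) e <- e + spec_bias(specs[[si]], params)
        }
      }
      e
    }, 0)
  }
  # two-body
  two_body <- list()
  all_choice_atoms <- c(lapply(choices, function(cc) lapply(cc, `[[`, "atoms")),
                        if (has_ts) list(ts_atoms))
  nlab <- length(labels)
  for (i in seq_len(nlab - 1L)) {
    for (j in seq((i + 1L), nlab)) {
      mat <- matrix(0, n_choices[i], n_choices[j])
      for (ci in seq_len(n_choices[i])) {
        Ai <- all_choice_atoms[[i]][[ci]]
        if (nrow(Ai) == 0L) next
        for (cj in seq_len(n_choices[j])) {
          Aj <- all_choice_atoms[[j]][[cj]]
          if (nrow(Aj) == 0L) next
          mat[ci, cj] <- pair_sum(Ai, Aj, params)
        }
      }
      if (has_ts && j == ts_idx && !is.null(specs) && any(spec_pos == i)) {
        for (si in which(spec_pos == i)) {
          for (ci in seq_len(n_choices[i])) {
            aug <- augment_model(bg_model, all_choice_atoms[[i]][[ci]])
            for (cj in seq_len(n_choices[j])) {
              gs <- geometry_check(aug, pose_ligand(ligand, pose_set[[cj]]),
                                   specs[[si]])
              if (gs$satisfied)
                mat[ci, cj] <- mat[ci, cj] + spec_bias(specs[[si]], params)
            }
          }
        }
      }
      two_body[[length(two_body) + 1L]] <- list(i = i, j = j, mat = mat)
    }
  }
  constant <- total_energy(bg_model, NULL, params,
                           context = list(background = bgatoms))$total
  structure(list(positions = labels, n_choices = n_choices,
                 one_body = one_body, two_body = two_body,
                 constant = constant, choices = choices,
                 pose_set = pose_set, ts_index = ts_idx,
                 bg_model = bg_model, bgatoms = bgatoms, ligand = ligand,
                 specs = specs, design = design,
                 fingerprint = params_fingerprint(params)),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> %d positions (%s); choices: %s; %.0f combinations\n",
              length(x$positions), paste(x$positions, collapse = ", "),
              paste(x$n_choices, collapse = "x"), prod(x$n_choices)))
  invisible(x)
}

#' Matrix energy of an assignment
#'
#' @param matrix an `interaction_matrix`.
#' @param assignment integer vector of 1-based choice indices per position.
#' @return total energy (kcal/mol) including the background constant.
#' @export
matrix_energy <- function(matrix, assignment) {
  stopifnot(length(assignment) == length(matrix$n_choices),
            all(assignment >= 1L), all(assignment <= matrix$n_choices))
  e <- matrix$constant
  for (p in seq_along(assignment)) e <- e + matrix$one_body[[p]][assignment[p]]
  for (tb in matrix$two_body) e <- e + tb$mat[assignment[tb$i], assignment[tb$j]]
  e
}

#' Simulated-annealing schedule
#'
#' Geometric cooling: the temperature starts at `t_start` (energy units,
#' kcal/mol), is multiplied by `cooling` after each stage of
#' `moves_per_stage` single-position Metropolis moves, and stops below
#' `t_end`.
#'
#' @param t_start,t_end temperatures, `t_start > t_end > 0`.
#' @param cooling per-stage factor in (0, 1).
#' @param moves_per_stage moves per stage; `NULL` uses 50 x (total choices).
#' @param seed integer seed for the portable 64-bit PRNG.
#' @return object of class `annealing_schedule`.
#' @export
annealing_schedule <- function(t_start = 100, t_end = 0.1, cooling = 0.95,
                               moves_per_stage = NULL, seed = 1L) {
  stopifnot(t_start > t_end, t_end > 0, cooling > 0, cooling < 1)
  structure(list(t_start = t_start, t_end = t_end, cooling = cooling,
                 moves_per_stage = moves_per_stage, seed = seed),
            class = "annealing_schedule")
}

new_repack_result <- function(assignment, energy, trace, seed,
                              breakdown = NULL, delta = NA_real_,
                              pose_index = NA_integer_, provenance = list(),
                              method = "anneal") {
  structure(list(assignment = assignment, energy = energy,
                 breakdown = breakdown, delta_vs_allgly = delta,
                 trace = trace, seed = seed, pose_index = pose_index,
                 provenance = provenance, method = method),
            class = "repack_result")
}

#' @export
print.repack_result <- function(x, ...) {
  cat(sprintf("<repack_result> (%s) energy %.4f kcal/mol; delta vs all-Gly %s\n",
              x$method, x$energy,
              if (is.na(x$delta_vs_allgly)) "NA" else sprintf("%.4f", x$delta_vs_allgly)))
  cat("  assignment:", paste(names(x$assignment), x$assignment, sep = "=",
                             collapse = " "), "\n")
  invisible(x)
}

#' Monte Carlo simulated-annealing search over an interaction matrix
#'
#' Single-position uniform resampling moves with Metropolis acceptance and
#' geometric cooling. The best assignment ever visited is returned; the same
#' seed gives a bit-identical result, and the best-so-far trace (one entry
#' per cooling stage) never increases.
#'
#' @param matrix an `interaction_matrix`.
#' @param schedule an [annealing_schedule()].
#' @return a `repack_result` (no breakdown; see [repack_sequence()]).
#' @export
anneal <- function(matrix, schedule = annealing_schedule()) {
  moves <- schedule$moves_per_stage
  if (is.null(moves)) moves <- 50L * sum(matrix$n_choices)
  pair_i <- vapply(matrix$two_body, `[[`, 0L, "i")
  pair_j <- vapply(matrix$two_body, `[[`, 0L, "j")
  mats <- lapply(matrix$two_body, `[[`, "mat")
  res <- anneal_core(as.integer(matrix$n_choices), matrix$one_body,
                     as.integer(pair_i), as.integer(pair_j), mats,
                     schedule$t_start, schedule$t_end, schedule$cooling,
                     as.integer(moves), as.double(schedule$seed),
                     rep(1L, length(matrix$n_choices)))
  assignment <- setNames(res$assignment, matrix$positions)
  new_repack_result(assignment, matrix$constant + res$energy,
                    matrix$constant + res$trace, schedule$seed)
}

#' Exhaustive enumeration oracle
#'
#' Finds the global minimum of an interaction matrix by enumerating every
#' assignment; ties are broken toward the lexicographically smallest
#' assignment. Guarded to at most one million combinations.
#'
#' @param matrix an `interaction_matrix`.
#' @return a `repack_result` with `method = "brute_force"`.
#' @export
brute_force <- function(matrix) {
  ncomb <- prod(matrix$n_choices)
  if (ncomb > 1e6) stop("brute_force guard: ", ncomb, " combinations exceed 1e6")
  npos <- length(matrix$n_choices)
  grid <- do.call(expand.grid,
                  c(rev(lapply(matrix$n_choices, seq_len)),
                    KEEP.OUT.ATTRS = FALSE))
  grid <- grid[, rev(seq_len(npos)), drop = FALSE]  # lexicographic row order
  e <- rep(matrix$constant, nrow(grid))
  for (p in seq_len(npos)) e <- e + matrix$one_body[[p]][grid[[p]]]
  for (tb in matrix$two_body)
    e <- e + tb$mat[cbind(grid[[tb$i]], grid[[tb$j]])]
  k <- which.min(e)  # first minimum = lexicographically smallest tie
  assignment <- setNames(as.integer(grid[k, ]), matrix$positions)
  new_repack_result(assignment, e[k], e[k], seed = NA_integer_,
                    method = "brute_force")
}

#' Materialize an assignment as a structure
#'
#' @param matrix an `interaction_matrix`.
#' @param assignment 1-based choice indices per position.
#' @return list with the rebuilt `structure_model`, the posed ligand table
#'   (or `NULL`) and the chosen `ts_pose` (or `NULL`).
#' @export
materialize_assignment <- function(matrix, assignment) {
  model <- matrix$bg_model
  npos <- nrow(matrix$design$positions)
  for (k in seq_len(npos))
    model <- augment_model(model, matrix$choices[[k]][[assignment[k]]]$atoms)
  pose <- NULL
  lig <- NULL
  if (matrix$ts_index > 0L) {
    pose <- matrix$pose_set[[assignment[matrix$ts_index]]]
    lig <- pose_ligand(matrix$ligand, pose)
  }
  list(model = model, ligand = lig, pose = pose)
}

#' All-Gly reference energy after ligand placement
#'
#' Energy of the template with every designable position truncated to
#' glycine, plus the placed transition-state pose, under the same
#' frozen-background solvation context used by the repacker.
#'
#' @param template a `structure_model`.
#' @param ligand ligand atom table (`NULL` for apo).
#' @param pose the placed `ts_pose` (`NULL` for apo).
#' @param design a [design_spec()].
#' @param params [energy_parameters()].
#' @param specs optional contact specs (bias included if satisfied).
#' @return an `energy_breakdown`.
#' @export
all_gly_reference <- function(template, ligand = NULL, pose = NULL, design,
                              params = energy_parameters(), specs = NULL) {
  gly <- strip_design_positions(template, design, types = "GLY")
  bg <- typed_protein_atoms(gly, params)
  lig <- if (!is.null(pose) && !is.null(ligand)) pose_ligand(ligand, pose)
  total_energy(gly, lig, params,
               context = list(background = bg, specs = specs))
}

#' Energy difference between a repacked structure and the all-Gly reference
#'
#' @param repacked a `repack_result` carrying its breakdown.
#' @param allgly_reference an `energy_breakdown` from [all_gly_reference()],
#'   computed with identical parameters (checked by fingerprint).
#' @return `repacked total - reference total`, kcal/mol.
#' @export
energy_delta <- function(repacked, allgly_reference) {
  bd <- if (inherits(repacked, "repack_result")) repacked$breakdown else repacked
  stopifnot(inherits(bd, "energy_breakdown"),
            inherits(allgly_reference, "energy_breakdown"))
  if (!identical(bd$params_fingerprint, allgly_reference$params_fingerprint))
    stop("parameter-set mismatch between repacked structure and reference")
  bd$total - allgly_reference$total
}

#' Repack a sequence over a set of starting transition-state poses
#'
#' Runs the simulated-annealing search once per starting pose (the pose's
#' rigid-body grid forming a TS super-position when
#' `design$ts_as_position = TRUE` and `perturb` is given) and returns the
#' single lowest-energy result, ties broken by (energy, pose index,
#' lexicographic assignment). The result carries the recomputed energy
#' breakdown and the energy difference against the all-Gly reference
#' obtained after ligand placement.
#'
#' @param template a `structure_model`.
#' @param ligand ligand atom table.
#' @param poses a `pose_library` or list of starting `ts_pose`s.
#' @param design a [design_spec()].
#' @param library a `rotamer_library`.
#' @param params [energy_parameters()].
#' @param schedule an [annealing_schedule()]; run `k` over the starting
#'   poses uses `seed + k - 1`.
#' @param perturb optional list of [perturb_pose_grid()] arguments
#'   (`trans_range`, `trans_step`, `rot_range`, `rot_step`) expanding each
#'   starting pose into its rigid-body grid.
#' @param specs optional contact specs for the geometry bias.
#' @return a `repack_result`.
#' @export
repack_sequence <- function(template, ligand, poses, design, library,
                            params = energy_parameters(),
                            schedule = annealing_schedule(),
                            perturb = NULL, specs = NULL) {
  if (inherits(poses, "pose_library")) poses <- poses$poses
  if (is.null(poses) || length(poses) == 0L) stop("no starting poses")
  best <- NULL
  best_matrix <- NULL
  best_start <- NULL
  for (k in seq_along(poses)) {
    pose_set <- if (design$ts_as_position && !is.null(perturb)) {
      do.call(perturb_pose_grid, c(list(poses[[k]]), perturb))$poses
    } else {
      list(poses[[k]])
    }
    m <- build_energy_matrix(template, pose_set, design, library, params,
                             ligand = ligand, specs = specs)
    sch <- schedule
    sch$seed <- schedule$seed + k - 1L
    r <- anneal(m, sch)
    r$pose_index <- k
    take <- is.null(best) || r$energy < best$energy - 1e-12 ||
      (abs(r$energy - best$energy) <= 1e-12 &&
         (k < best$pose_index ||
            (k == best$pose_index &&
               paste(r$assignment, collapse = ",") <
               paste(best$assignment, collapse = ","))))
    if (take) {
      best <- r
      best_matrix <- m
      best_start <- poses[[k]]
    }
  }
  mat <- materialize_assignment(best_matrix, best$assignment)
  bd <- total_energy(mat$model, mat$ligand, params,
                     context = list(background = best_matrix$bgatoms,
                                    specs = specs))
  ref <- all_gly_reference(template, ligand, best_start, design, params,
                           specs = specs)
  best$breakdown <- bd
  best$delta_vs_allgly <- bd$total - ref$total
  best$provenance <- list(starting_pose_id = best_start$id,
                          pose_index = best$pose_index,
                          fingerprint = best_matrix$fingerprint,
                          allgly_total = ref$total)
  best
}
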