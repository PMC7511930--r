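# Design across ensemble backbone templates (ensemble-refinement members or
# MD snapshots): per-member ligand placement + repacking, delta-vs-all-Gly
# ranking, trajectory subsampling and superposition RMSD to a reference.

#' Run the design protocol over every member of a backbone ensemble
#'
#' For each member: [generate_poses()], [select_lowest()]
#' (`poses_per_member`, default the single lowest-energy pose), then
#' [repack_sequence()]. Members are ranked ascending by their energy
#' difference to the all-Gly reference. Per-member seeds are derived as
#' `xor(seed, member_index - 1)` so runs are reproducible yet members are
#' decorrelated, and a single-member ensemble reproduces
#' [repack_sequence()] exactly. A member that fails (e.g. missing a design
#' position) is flagged and the run continues.
#'
#' @param members list of `structure_model` (e.g. from [read_ensemble()]).
#' @param ligand ligand atom table.
#' @param specs list of [contact_spec()].
#' @param design a [design_spec()].
#' @param library a `rotamer_library`.
#' @param params [energy_parameters()].
#' @param schedule an [annealing_schedule()].
#' @param poses_per_member starting poses retained per member.
#' @param dof_grids optional placement DOF grids (see [generate_poses()]).
#' @param perturb optional rigid-body grid arguments (see
#'   [repack_sequence()]).
#' @param clash_threshold placement clash filter, Angstrom.
#' @return an `ensemble_design_report`: per-member records, ranking by
#'   delta, the global best member id, and the full `repack_result`s.
#' @export
design_over_ensemble <- function(members, ligand, specs, design, library,
                                 params = energy_parameters(),
                                 schedule = annealing_schedule(),
                                 poses_per_member = 1L,
                                 dof_grids = NULL, perturb = NULL,
                                 clash_threshold = 2.0) {
  if (length(members) == 0L) stop("empty ensemble: no members to design on")
  n <- length(members)
  records <- data.frame(member = integer(n), model_id = integer(n),
                        source_tag = character(n), failed = logical(n),
                        message = character(n), best_pose_id = integer(n),
                        best_energy = numeric(n), delta_vs_allgly = numeric(n),
                        stringsAsFactors = FALSE)
  results <- vector("list", n)
  for (k in seq_len(n)) {
    m <- members[[k]]
    records$member[k] <- k
    records$model_id[k] <- m$model_id
    records$source_tag[k] <- m$source_tag
    sch <- schedule
    sch$seed <- bitwXor(as.integer(schedule$seed), k - 1L)
    out <- tryCatch({
      lib_poses <- suppressWarnings(
        generate_poses(m, ligand, specs, dof_grids, params, clash_threshold))
      if (length(lib_poses) == 0L) stop("no poses survived placement")
      starts <- suppressWarnings(select_lowest(lib_poses, poses_per_member))
      repack_sequence(m, ligand, starts, design, library, params, sch,
                      perturb = perturb, specs = specs)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      records$failed[k] <- TRUE
      records$message[k] <- conditionMessage(out)
      records$best_pose_id[k] <- NA_integer_
      records$best_energy[k] <- NA_real_
      records$delta_vs_allgly[k] <- NA_real_
    } else {
      results[[k]] <- out
      records$best_pose_id[k] <- out$provenance$starting_pose_id
      records$best_energy[k] <- out$energy
      records$delta_vs_allgly[k] <- out$delta_vs_allgly
    }
  }
  ok <- which(!records$failed)
  ranking <- ok[order(records$delta_vs_allgly[ok], ok)]
  structure(list(records = records, results = results, ranking = ranking,
                 best_member = if (length(ranking)) ranking[1L] else NA_integer_,
                 n_failed = sum(records$failed),
                 seed = schedule$seed),
            class = "ensemble_design_report")
}

#' @export
print.ensemble_design_report <- function(x, ...) {
  cat(sprintf("<ensemble_design_report> %d members (%d failed); best member %s\n",
              nrow(x$records), x$n_failed, x$best_member))
  print(x$records[x$ranking, c("member", "model_id", "best_energy",
                               "delta_vs_allgly")], row.names = FALSE)
  invisible(x)
}

#' Subsample a trajectory at a fixed time interval
#'
#' Selects the frames nearest to `start`, `start + interval`, ... within the
#' trajectory span, e.g. a 500-ns production run sampled every 10 ns from
#' 10 ns yields 50 snapshots.
#'
#' @param frame_times frame times in ns, sorted ascending.
#' @param interval sampling interval, ns (> 0).
#' @param start first sample time, ns (default 0).
#' @return integer indices of the selected frames;
#'   `floor((span - start)/interval) + 1` of them.
#' @export
subsample_trajectory <- function(frame_times, interval, start = 0) {
  if (length(frame_times) == 0L) stop("empty trajectory")
  if (is.unsorted(frame_times)) stop("frame times must be sorted ascending")
  if (interval <= 0) stop("interval must be > 0")
  t0 <- min(frame_times)
  span <- max(frame_times) - t0
  targets <- t0 + seq(start, max(start, span), by = interval)
  targets <- targets[targets <= t0 + span + 1e-9]
  if (length(targets) == 0L) targets <- t0 + start
  vapply(targets, function(tt) which.min(abs(frame_times - tt)), 0L)
}

#' Superposition RMSD of a member to a reference structure
#'
#' Atoms are paired by (chain, residue number, insertion code, atom name)
#' over the selection; with `superpose = TRUE` (default) the member is first
#' fitted onto the reference by least-squares (Kabsch) superposition.
#'
#' @param member,reference `structure_model`s.
#' @param selection atom-name set (default C-alpha only).
#' @param superpose fit before measuring.
#' @return RMSD in Angstrom.
#' @export
rmsd_to_reference <- function(member, reference, selection = "CA",
                              superpose = TRUE) {
  sel <- function(m) {
    a <- m$atoms[m$atoms$name %in% selection & !m$atoms$is_h, , drop = FALSE]
    key <- paste(a$chain, a$resno, a$ins, a$name, sep = "|")
    dup <- duplicated(key)
    a <- a[!dup, , drop = FALSE]
    rownames(a) <- key[!dup]
    a
  }
  a <- sel(member)
  b <- sel(reference)
  common <- intersect(rownames(a), rownames(b))
  un <- c(setdiff(rownames(a), common), setdiff(rownames(b), common))
  if (length(un) > 0L)
    stop("unpaired atoms in RMSD selection: ", paste(un, collapse = ", "))
  if (length(common) == 0L) stop("empty RMSD selection")
  ma <- as.matrix(a[common, c("x", "y", "z")])
  mb <- as.matrix(b[common, c("x", "y", "z")])
  if (superpose && length(common) >= 3L) ma <- apply_transform(ma, kabsch(ma, mb))
  if (superpose && length(common) < 3L) {
    # too few atoms for a unique rotation: translate centroids only
    ma <- sweep(ma, 2, colMeans(ma) - colMeans(mb))
  }
  coord_rmsd(ma, mb)
}
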