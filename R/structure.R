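# PDB structure container and fixed-column reader/writer.
#
# A structure_model holds one backbone template: a protein atom table, a
# ligand (HETATM) atom table kept separate from the protein chains, and
# optional waters. Coordinates are Angstrom in the deposited frame; residue
# numbering follows the file (no renumbering) so positions like Asp127 keep
# their literature labels.

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA1 <- setNames(names(AA3), AA3)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Alternate-location conformer policy
#'
#' Controls how alternate conformers are resolved when reading a structure.
#' The default keeps, for every residue, the single conformer whose summed
#' occupancy is highest; occupancy ties are broken by taking the
#' lexicographically smallest altloc tag. Blank-altloc atoms are treated as a
#' single full-occupancy conformer and always retained.
#'
#' @param chain optional chain identifier(s) to retain (e.g. `"A"`); `NULL`
#'   keeps all chains.
#' @param altloc_rule one of `"highest-occupancy"` (default), `"all"` (keep
#'   every conformer) or `"explicit"` (keep `explicit_tag` plus blanks).
#' @param explicit_tag altloc tag used when `altloc_rule = "explicit"`.
#' @param keep_waters keep HOH/WAT residues (default `FALSE`; the design
#'   protocol works on protein heavy atoms only).
#' @param keep_hydrogens retain hydrogen atoms if present (they are flagged
#'   in the atom table either way).
#' @return an object of class `conformer_policy`.
#' @export
conformer_policy <- function(chain = NULL,
                             altloc_rule = c("highest-occupancy", "all", "explicit"),
                             explicit_tag = "A",
                             keep_waters = FALSE,
                             keep_hydrogens = TRUE) {
  altloc_rule <- match.arg(altloc_rule)
  if (altloc_rule == "explicit" && (length(explicit_tag) != 1L || nchar(explicit_tag) != 1L))
    stop("explicit_tag must be a single character")
  structure(list(chain = chain, altloc_rule = altloc_rule,
                 explicit_tag = explicit_tag, keep_waters = keep_waters,
                 keep_hydrogens = keep_hydrogens),
            class = "conformer_policy")
}

parse_float <- function(s, line_no, what) {
  s <- trimws(s)
  if (s == "") return(NA_real_)
  x <- suppressWarnings(as.numeric(s))
  if (is.na(x)) stop(sprintf("PDB parse error at line %d: bad %s field '%s'", line_no, what, s))
  x
}

guess_element <- function(name) {
  # strip digits/primes, first alphabetic character(s)
  core <- gsub("[0-9']", "", name)
  core <- trimws(core)
  if (core == "") return("X")
  two <- toupper(substr(core, 1, 2))
  if (two %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "SE")) return(two)
  toupper(substr(core, 1, 1))
}

parse_pdb_lines <- function(lines) {
  idx <- grep("^(ATOM  |HETATM)", lines)
  if (length(idx) == 0L) stop("PDB parse error: no ATOM/HETATM records found")
  rec <- lines[idx]
  # pad short lines so fixed-column extraction is total
  rec <- formatC(rec, width = 80, flag = "-")
  n <- length(rec)
  df <- data.frame(
    record  = trimws(substr(rec, 1, 6)),
    serial  = suppressWarnings(as.integer(substr(rec, 7, 11))),
    name    = trimws(substr(rec, 13, 16)),
    altloc  = gsub(" ", "", substr(rec, 17, 17)),
    res_type = trimws(substr(rec, 18, 20)),
    chain   = trimws(substr(rec, 22, 22)),
    resno   = suppressWarnings(as.integer(substr(rec, 23, 26))),
    ins     = gsub(" ", "", substr(rec, 27, 27)),
    x = NA_real_, y = NA_real_, z = NA_real_,
    occ = NA_real_, b = NA_real_,
    element = trimws(substr(rec, 77, 78)),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(n)) {
    ln <- idx[k]
    df$x[k]   <- parse_float(substr(rec[k], 31, 38), ln, "x coordinate")
    df$y[k]   <- parse_float(substr(rec[k], 39, 46), ln, "y coordinate")
    df$z[k]   <- parse_float(substr(rec[k], 47, 54), ln, "z coordinate")
    df$occ[k] <- parse_float(substr(rec[k], 55, 60), ln, "occupancy")
    df$b[k]   <- parse_float(substr(rec[k], 61, 66), ln, "B-factor")
    if (is.na(df$resno[k]))
      stop(sprintf("PDB parse error at line %d: bad residue number", ln))
    if (is.na(df$x[k]) || is.na(df$y[k]) || is.na(df$z[k]))
      stop(sprintf("PDB parse error at line %d: missing coordinate", ln))
  }
  df$occ[is.na(df$occ)] <- 1
  df$b[is.na(df$b)] <- 0
  miss <- df$element == ""
  if (any(miss)) df$element[miss] <- vapply(df$name[miss], guess_element, "")
  df$element <- toupper(df$element)
  df$is_h <- df$element == "H"
  df
}

apply_policy <- function(atoms, policy) {
  if (!isTRUE(policy$keep_waters))
    atoms <- atoms[!atoms$res_type %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  if (!is.null(policy$chain)) {
    atoms <- atoms[atoms$chain %in% policy$chain, , drop = FALSE]
    if (nrow(atoms) == 0L)
      stop("empty selection: no atoms left after chain filter")
  }
  if (!policy$keep_hydrogens) atoms <- atoms[!atoms$is_h, , drop = FALSE]
  if (policy$altloc_rule == "all") return(atoms)
  if (policy$altloc_rule == "explicit") {
    keep <- atoms$altloc == "" | atoms$altloc == policy$explicit_tag
    return(atoms[keep, , drop = FALSE])
  }
  # highest-occupancy, per residue, lexicographic tie-break
  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[atoms$altloc != ""])) {
    sel <- key == k & atoms$altloc != ""
    tags <- sort(unique(atoms$altloc[sel]))
    tot <- vapply(tags, function(tg) sum(atoms$occ[sel & atoms$altloc == tg]), 0)
    best <- tags[tot == max(tot)][1L]  # sorted, so ties pick the smallest tag
    keep[sel & atoms$altloc != best] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

new_structure_model <- function(atoms, model_id = 1L, source_tag = "single") {
  is_water <- atoms$res_type %in% c("HOH", "WAT", "DOD")
  is_het <- atoms$record == "HETATM" & !is_water
  m <- structure(list(
    model_id = as.integer(model_id),
    source_tag = source_tag,
    atoms = atoms[!is_het & !is_water, , drop = FALSE],
    ligand = atoms[is_het, , drop = FALSE],
    waters = atoms[is_water, , drop = FALSE]
  ), class = "structure_model")
  validate_structure_model(m)
  m
}

validate_structure_model <- function(m) {
  a <- m$atoms
  if (nrow(a) + nrow(m$ligand) == 0L) stop("structure has no atoms")
  if (any(!is.finite(c(a$x, a$y, a$z)))) stop("non-finite coordinates")
  if (any(a$occ < 0 | a$occ > 1)) stop("occupancy outside [0, 1]")
  if (any(a$b < 0)) stop("negative B-factor")
  dup <- duplicated(paste(a$chain, a$resno, a$ins, a$name, a$altloc, sep = "|"))
  if (any(dup))
    stop("duplicate atom records: ",
         paste(unique(paste0(a$chain[dup], "/", a$resno[dup], "/", a$name[dup])), collapse = ", "))
  invisible(m)
}

#' Read a protein/ligand structure from PDB text
#'
#' Parses fixed-column ATOM/HETATM records, applies the conformer policy
#' (chain filter, alternate-location resolution, water handling) and returns
#' a single [structure_model]. HETATM ligand records are stored in a
#' separate `ligand` table, never merged into the protein chains; waters are
#' dropped unless the policy retains them.
#'
#' @param pdb_text character scalar or vector of PDB lines; alternatively
#'   give `path`.
#' @param policy a [conformer_policy()].
#' @param path optional file path read with `readLines()`.
#' @param model_id,source_tag provenance fields stored on the result;
#'   `source_tag` is one of `"single"`, `"ensemble-refinement"`,
#'   `"md-snapshot"`.
#' @return a `structure_model`.
#' @export
read_structure <- function(pdb_text = NULL, policy = conformer_policy(),
                           path = NULL, model_id = 1L, source_tag = "single") {
  lines <- pdb_lines(pdb_text, path)
  nmodel <- grep("^MODEL", lines)
  if (length(nmodel) > 1L) {
    warning("multi-MODEL file passed to read_structure(); using the first MODEL ",
            "(use read_ensemble() for the full ensemble)")
    endm <- grep("^ENDMDL", lines)
    if (length(endm) == 0L) stop("PDB parse error: unterminated MODEL block")
    lines <- lines[seq(nmodel[1L], endm[1L])]
  }
  atoms <- apply_policy(parse_pdb_lines(lines), policy)
  if (nrow(atoms) == 0L) stop("empty selection: no atoms retained by policy")
  new_structure_model(atoms, model_id = model_id, source_tag = source_tag)
}

pdb_lines <- function(pdb_text, path) {
  if (is.null(pdb_text)) {
    if (is.null(path)) stop("give pdb_text or path")
    return(readLines(path, warn = FALSE))
  }
  if (length(pdb_text) == 1L && grepl("\n", pdb_text))
    return(strsplit(pdb_text, "\n", fixed = TRUE)[[1L]])
  pdb_text
}

#' Read a multi-MODEL PDB ensemble
#'
#' Splits MODEL/ENDMDL framed text (as produced by ensemble refinement or MD
#' snapshot extraction) into one [structure_model] per member. A file
#' without MODEL records yields a single-member list. Members whose residue
#' key sets differ from the first member trigger a warning.
#'
#' @inheritParams read_structure
#' @return list of `structure_model`, `model_id` taken from the MODEL record.
#' @export
read_ensemble <- function(pdb_text = NULL, policy = conformer_policy(),
                          path = NULL, source_tag = "ensemble-refinement") {
  lines <- pdb_lines(pdb_text, path)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    return(list(read_structure(lines, policy, source_tag = source_tag)))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts))
    stop("PDB parse error: unterminated MODEL block")
  members <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    id <- suppressWarnings(as.integer(trimws(substr(lines[starts[i]], 7, 80))))
    if (is.na(id)) id <- i
    block <- lines[seq(starts[i] + 1L, ends[i] - 1L)]
    atoms <- apply_policy(parse_pdb_lines(block), policy)
    members[[i]] <- new_structure_model(atoms, model_id = id, source_tag = source_tag)
  }
  keys0 <- residue_keys(members[[1L]])
  same <- vapply(members, function(m) identical(residue_keys(m), keys0), TRUE)
  if (!all(same))
    warning("ensemble members do not share identical residue keys: member(s) ",
            paste(which(!same), collapse = ", "))
  members
}

#' Residue keys of a structure
#' @param model a `structure_model`.
#' @return character vector `chain|resno|ins` in file order.
#' @export
residue_keys <- function(model) {
  a <- model$atoms
  unique(paste(a$chain, a$resno, a$ins, sep = "|"))
}

format_pdb_atom <- function(rec, serial, name, altloc, res, chain, resno, ins,
                            x, y, z, occ, b, element) {
  if (nchar(name) > 4L) stop("atom name '", name, "' exceeds the PDB field width")
  nm <- if (nchar(name) == 4L || nchar(element) == 2L) name
        else paste0(" ", name)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, ifelse(altloc == "", " ", altloc), res, chain,
          resno, ifelse(ins == "", " ", ins), x, y, z, occ, b, element)
}

#' Write a structure as PDB text
#'
#' Coordinates are written to the PDB 3-decimal convention and occupancy and
#' B-factor to 2 decimals, so `read_structure(write_structure(m))` preserves
#' them at format precision and writing a re-read model is byte-identical.
#'
#' @param model a `structure_model`.
#' @param path optional file to write; the text is returned invisibly then.
#' @return character vector of PDB lines.
#' @export
write_structure <- function(model, path = NULL) {
  stopifnot(inherits(model, "structure_model"))
  validate_structure_model(model)
  blocks <- list(list(model$atoms, "ATOM"), list(model$ligand, "HETATM"),
                 list(model$waters, "HETATM"))
  out <- character(0)
  serial <- 0L
  last_chain <- NULL
  for (blk in blocks) {
    a <- blk[[1L]]
    if (nrow(a) == 0L) next
    for (k in seq_len(nrow(a))) {
      serial <- serial + 1L
      out <- c(out, format_pdb_atom(blk[[2L]], serial, a$name[k], a$altloc[k],
                                    a$res_type[k], a$chain[k], a$resno[k],
                                    a$ins[k], a$x[k], a$y[k], a$z[k],
                                    a$occ[k], a$b[k], a$element[k]))
    }
    if (identical(blk[[2L]], "ATOM")) out <- c(out, "TER")
  }
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Thread a mutation set onto a template
#'
#' Applies point mutations to a structure: residue types are updated and
#' side chains beyond the beta carbon are stripped, pending rebuilding by the
#' rotamer machinery. Backbone coordinates are untouched. Every mutation's
#' wild-type letter must match the template at that position.
#'
#' @param model a `structure_model`.
#' @param mutations a [parse_mutations()] set or character tokens like
#'   `"K50Q"`.
#' @param chain chain to mutate (default: all chains carrying the position).
#' @return the mutated `structure_model`.
#' @export
thread_sequence <- function(model, mutations, chain = NULL) {
  if (is.character(mutations)) mutations <- parse_mutations(mutations)
  a <- model$atoms
  for (k in seq_len(nrow(mutations$tokens))) {
    tok <- mutations$tokens[k, ]
    sel <- a$resno == tok$pos & (is.null(chain) | a$chain %in% chain)
    if (!any(sel))
      stop("position ", tok$pos, " not found in template")
    found <- unique(a$res_type[sel])
    want <- AA3[[tok$wt]]
    if (!identical(found, want))
      stop(sprintf("identity check failed at position %d: template has %s, mutation %s expects %s",
                   tok$pos, paste(found, collapse = "/"), tok$token, want))
    new3 <- AA3[[tok$mut]]
    a$res_type[sel] <- new3
    keep_names <- if (new3 == "GLY") BACKBONE_ATOMS else c(BACKBONE_ATOMS, "CB")
    drop <- sel & !(a$name %in% keep_names) & !a$is_h
    dropH <- sel & a$is_h & !(a$name %in% c("H", "HA"))
    a <- a[!(drop | dropH), , drop = FALSE]
  }
  model$atoms <- a
  validate_structure_model(model)
  model
}

# Resolve "chain/resno/atom" references (optionally "chain/resno/ins/atom")
# to a coordinate row in the protein atom table.
resolve_atom_ref <- function(model, ref) {
  parts <- strsplit(ref, "/", fixed = TRUE)[[1L]]
  if (length(parts) == 3L) parts <- c(parts[1:2], "", parts[3L])
  if (length(parts) != 4L) stop("bad atom reference '", ref, "' (chain/resno/atom)")
  a <- model$atoms
  i <- which(a$chain == parts[1L] & a$resno == as.integer(parts[2L]) &
             a$ins == parts[3L] & a$name == parts[4L])
  if (length(i) == 0L) stop("unresolvable atom reference '", ref, "'")
  i[1L]
}

residue_atoms <- function(model, chain, resno, ins = "") {
  a <- model$atoms
  a[a$chain == chain & a$resno == resno & a$ins == ins, , drop = FALSE]
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> id %d (%s): %d protein atoms / %d residues, %d ligand atoms, %d water atoms\n",
              x$model_id, x$source_tag, nrow(x$atoms), length(residue_keys(x)),
              nrow(x$ligand), nrow(x$waters)))
  invisible(x)
}
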