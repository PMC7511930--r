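# Backbone-independent rotamer library and ideal-geometry side-chain builder.
#
# The library dialect is a TSV with header
#   res_type  prob  chi1 chi2 chi3 chi4  sd1 sd2 sd3 sd4
# where unused chi columns are empty or NA. Angles are degrees in
# (-180, 180]. The loader accepts any file in this dialect (e.g. a
# user-supplied conversion of the Dunbrack 2002 backbone-independent
# library); the package ships only a small generic library for tests and
# demos via make_toy_rotamer_library().

N_CHI <- c(ALA = 0L, ARG = 4L, ASN = 2L, ASP = 2L, CYS = 1L, GLN = 3L,
           GLU = 3L, GLY = 0L, HIS = 2L, ILE = 2L, LEU = 2L, LYS = 4L,
           MET = 3L, PHE = 2L, PRO = 2L, SER = 1L, THR = 1L, TRP = 2L,
           TYR = 2L, VAL = 1L)

# Atom-name quadruples defining each chi dihedral.
CHI_ATOMS <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"), c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  PRO = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1"))
)

# Ideal side-chain internal coordinates: one table, a constant of the
# artifact. Each entry: atom, frame atoms (a, b, c with the new atom bonded
# to c), bond length (A), bond angle at c (deg), and the torsion rule --
# "chiK" (use the K-th requested chi), a numeric string offset "chiK+D"
# (branch at fixed offset from chiK), or a fixed value.
sc_row <- function(name, a, b, c, len, ang, tors) {
  list(name = name, a = a, b = b, c = c, len = len, ang = ang, tors = tors)
}

SC_TOPOLOGY <- list(
  SER = list(sc_row("OG", "N", "CA", "CB", 1.417, 110.8, "chi1")),
  CYS = list(sc_row("SG", "N", "CA", "CB", 1.808, 113.8, "chi1")),
  THR = list(sc_row("OG1", "N", "CA", "CB", 1.433, 109.5, "chi1"),
             sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-122")),
  VAL = list(sc_row("CG1", "N", "CA", "CB", 1.527, 110.5, "chi1"),
             sc_row("CG2", "N", "CA", "CB", 1.527, 110.5, "chi1+122")),
  ILE = list(sc_row("CG1", "N", "CA", "CB", 1.530, 110.4, "chi1"),
             sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-122"),
             sc_row("CD1", "CA", "CB", "CG1", 1.513, 113.8, "chi2")),
  LEU = list(sc_row("CG", "N", "CA", "CB", 1.530, 116.3, "chi1"),
             sc_row("CD1", "CA", "CB", "CG", 1.521, 110.7, "chi2"),
             sc_row("CD2", "CA", "CB", "CG", 1.521, 110.7, "chi2+122")),
  ASP = list(sc_row("CG", "N", "CA", "CB", 1.516, 112.6, "chi1"),
             sc_row("OD1", "CA", "CB", "CG", 1.249, 118.4, "chi2"),
             sc_row("OD2", "CA", "CB", "CG", 1.249, 118.4, "chi2+180")),
  ASN = list(sc_row("CG", "N", "CA", "CB", 1.516, 112.6, "chi1"),
             sc_row("OD1", "CA", "CB", "CG", 1.231, 120.8, "chi2"),
             sc_row("ND2", "CA", "CB", "CG", 1.328, 116.4, "chi2+180")),
  GLU = list(sc_row("CG", "N", "CA", "CB", 1.530, 114.1, "chi1"),
             sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, "chi2"),
             sc_row("OE1", "CB", "CG", "CD", 1.249, 118.4, "chi3"),
             sc_row("OE2", "CB", "CG", "CD", 1.249, 118.4, "chi3+180")),
  GLN = list(sc_row("CG", "N", "CA", "CB", 1.530, 114.1, "chi1"),
             sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, "chi2"),
             sc_row("OE1", "CB", "CG", "CD", 1.231, 120.8, "chi3"),
             sc_row("NE2", "CB", "CG", "CD", 1.328, 116.4, "chi3+180")),
  MET = list(sc_row("CG", "N", "CA", "CB", 1.530, 114.1, "chi1"),
             sc_row("SD", "CA", "CB", "CG", 1.803, 112.7, "chi2"),
             sc_row("CE", "CB", "CG", "SD", 1.791, 100.9, "chi3")),
  LYS = list(sc_row("CG", "N", "CA", "CB", 1.530, 114.1, "chi1"),
             sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, "chi2"),
             sc_row("CE", "CB", "CG", "CD", 1.520, 111.3, "chi3"),
             sc_row("NZ", "CG", "CD", "CE", 1.489, 111.9, "chi4")),
  ARG = list(sc_row("CG", "N", "CA", "CB", 1.530, 114.1, "chi1"),
             sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, "chi2"),
             sc_row("NE", "CB", "CG", "CD", 1.461, 112.0, "chi3"),
             sc_row("CZ", "CG", "CD", "NE", 1.329, 124.2, "chi4"),
             sc_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, "0"),
             sc_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, "180")),
  PHE = list(sc_row("CG", "N", "CA", "CB", 1.502, 113.8, "chi1"),
             sc_row("CD1", "CA", "CB", "CG", 1.384, 120.8, "chi2"),
             sc_row("CD2", "CA", "CB", "CG", 1.384, 120.8, "chi2+180"),
             sc_row("CE1", "CB", "CG", "CD1", 1.382, 121.0, "180"),
             sc_row("CE2", "CB", "CG", "CD2", 1.382, 121.0, "180"),
             sc_row("CZ", "CG", "CD1", "CE1", 1.382, 120.0, "0")),
  TYR = list(sc_row("CG", "N", "CA", "CB", 1.502, 113.8, "chi1"),
             sc_row("CD1", "CA", "CB", "CG", 1.384, 120.8, "chi2"),
             sc_row("CD2", "CA", "CB", "CG", 1.384, 120.8, "chi2+180"),
             sc_row("CE1", "CB", "CG", "CD1", 1.382, 121.0, "180"),
             sc_row("CE2", "CB", "CG", "CD2", 1.382, 121.0, "180"),
             sc_row("CZ", "CG", "CD1", "CE1", 1.382, 120.0, "0"),
             sc_row("OH", "CD1", "CE1", "CZ", 1.376, 119.9, "180")),
  TRP = list(sc_row("CG", "N", "CA", "CB", 1.498, 113.6, "chi1"),
             sc_row("CD1", "CA", "CB", "CG", 1.365, 126.9, "chi2"),
             sc_row("CD2", "CA", "CB", "CG", 1.433, 126.7, "chi2+180"),
             sc_row("NE1", "CB", "CG", "CD1", 1.374, 110.2, "180"),
             sc_row("CE2", "CB", "CG", "CD2", 1.409, 107.2, "180"),
             sc_row("CE3", "CB", "CG", "CD2", 1.398, 133.9, "0"),
             sc_row("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, "180"),
             sc_row("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, "180"),
             sc_row("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, "0")),
  HIS = list(sc_row("CG", "N", "CA", "CB", 1.492, 113.8, "chi1"),
             sc_row("ND1", "CA", "CB", "CG", 1.380, 122.7, "chi2"),
             sc_row("CD2", "CA", "CB", "CG", 1.354, 131.0, "chi2+180"),
             sc_row("CE1", "CB", "CG", "ND1", 1.326, 109.2, "180"),
             sc_row("NE2", "CB", "CG", "CD2", 1.373, 107.2, "180")),
  PRO = list(sc_row("CG", "N", "CA", "CB", 1.495, 104.5, "chi1"),
             sc_row("CD", "CA", "CB", "CG", 1.507, 106.1, "chi2"))
)

CHI_COLS <- paste0("chi", 1:4)
SD_COLS <- paste0("sd", 1:4)

#' Load a backbone-independent rotamer library
#'
#' @param table_text character scalar/vector with the TSV content, or give
#'   `path`.
#' @param path optional file path.
#' @return an object of class `rotamer_library` wrapping the record table.
#'   Probabilities per residue type need not sum to one (library subsetting
#'   is allowed); see [library_records()] for a normalized view.
#' @export
load_rotamer_library <- function(table_text = NULL, path = NULL) {
  if (is.null(table_text)) {
    stopifnot(!is.null(path))
    table_text <- readLines(path, warn = FALSE)
  }
  if (length(table_text) == 1L && grepl("\n", table_text))
    table_text <- strsplit(table_text, "\n", fixed = TRUE)[[1L]]
  df <- read.delim(text = paste(table_text, collapse = "\n"),
                   stringsAsFactors = FALSE)
  need <- c("res_type", "prob", CHI_COLS, SD_COLS)
  if (!all(need %in% names(df)))
    stop("rotamer library schema error: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$res_type <- toupper(df$res_type)
  for (k in seq_len(nrow(df))) {
    rt <- df$res_type[k]
    if (!rt %in% names(N_CHI))
      stop("rotamer library schema error: unknown residue type ", rt)
    nchi <- N_CHI[[rt]]
    have <- !is.na(unlist(df[k, CHI_COLS]))
    if (!identical(unname(have), seq_len(4L) <= nchi))
      stop("rotamer library schema error: ", rt, " record has chi values inconsistent with its ",
           nchi, " chi angle(s)")
    sd_have <- !is.na(unlist(df[k, SD_COLS]))
    if (any(sd_have & !have))
      stop("rotamer library schema error: sd given for absent chi in ", rt, " record")
  }
  for (cc in CHI_COLS) df[[cc]] <- wrap_angle(df[[cc]])
  for (cc in SD_COLS) df[[cc]][is.na(df[[cc]]) & !is.na(df[[sub("sd", "chi", cc)]])] <- 0
  if (any(df$prob < 0, na.rm = TRUE)) stop("rotamer library schema error: negative probability")
  structure(list(records = df), class = "rotamer_library")
}

#' Rotamer records for one residue type
#'
#' @param lib a `rotamer_library`.
#' @param res_type 3-letter code.
#' @param normalize if `TRUE`, rescale the `prob` column to sum to one within
#'   the residue type.
#' @return data frame of records.
#' @export
library_records <- function(lib, res_type, normalize = FALSE) {
  stopifnot(inherits(lib, "rotamer_library"))
  r <- lib$records[lib$records$res_type == toupper(res_type), , drop = FALSE]
  if (normalize && nrow(r) > 0L && sum(r$prob) > 0) r$prob <- r$prob / sum(r$prob)
  r
}

#' @export
print.rotamer_library <- function(x, ...) {
  cat(sprintf("<rotamer_library> %d records, %d residue types\n",
              nrow(x$records), length(unique(x$records$res_type))))
  invisible(x)
}

#' Chi-expansion policy
#'
#' Rotamer sampling is densified by expanding selected chi angles to
#' mean - n_sd*sd, mean, mean + n_sd*sd. The default (+/- 1 standard
#' deviation around chi1 and chi2) follows common enzyme-design practice.
#'
#' @param n_sd number of standard deviations (>= 0).
#' @param expanded_chis chi indices to expand.
#' @return object of class `expansion_policy`.
#' @export
expansion_policy <- function(n_sd = 1, expanded_chis = c(1L, 2L)) {
  stopifnot(n_sd >= 0)
  structure(list(n_sd = n_sd, expanded_chis = as.integer(expanded_chis)),
            class = "expansion_policy")
}

#' Expand a rotamer record around its chi means
#'
#' Each expanded chi takes the values mean - n_sd*sd, mean, mean + n_sd*sd;
#' unexpanded chis stay at their means. Duplicate variants (sd = 0) are
#' collapsed and angles re-wrapped into (-180, 180]. The parent probability
#' is carried unchanged onto every variant (no re-weighting).
#'
#' @param record a single library record (1-row data frame as returned by
#'   [library_records()]).
#' @param policy an [expansion_policy()].
#' @return data frame of variant records.
#' @export
expand_rotamer <- function(record, policy = expansion_policy()) {
  stopifnot(nrow(record) == 1L)
  nchi <- N_CHI[[record$res_type]]
  if (nchi == 0L) return(record)
  grids <- vector("list", nchi)
  for (i in seq_len(nchi)) {
    mu <- record[[CHI_COLS[i]]]
    sdv <- record[[SD_COLS[i]]]
    if (i %in% policy$expanded_chis && policy$n_sd > 0 && !is.na(sdv) && sdv > 0) {
      grids[[i]] <- wrap_angle(c(mu - policy$n_sd * sdv, mu, mu + policy$n_sd * sdv))
    } else {
      grids[[i]] <- mu
    }
  }
  combos <- do.call(expand.grid, c(rev(grids), KEEP.OUT.ATTRS = FALSE))
  combos <- combos[, rev(seq_len(nchi)), drop = FALSE]  # chi1 varies slowest
  combos <- unique(combos)
  out <- record[rep(1L, nrow(combos)), , drop = FALSE]
  for (i in seq_len(nchi)) out[[CHI_COLS[i]]] <- combos[[i]]
  rownames(out) <- NULL
  out
}

record_chi <- function(record) {
  nchi <- N_CHI[[record$res_type]]
  if (nchi == 0L) return(numeric(0))
  as.numeric(unlist(record[1L, CHI_COLS[seq_len(nchi)]]))
}

resolve_torsion <- function(tors, chi_values) {
  if (grepl("^chi", tors)) {
    m <- regmatches(tors, regexec("^chi([0-9])([+-][0-9.]+)?$", tors))[[1L]]
    k <- as.integer(m[2L])
    off <- if (m[3L] == "") 0 else as.numeric(m[3L])
    return(wrap_angle(chi_values[k] + off))
  }
  as.numeric(tors)
}

#' Build side-chain atoms for a residue from ideal internal coordinates
#'
#' Places the beta carbon by ideal tetrahedral geometry off the backbone and
#' grows the remaining heavy atoms from a packaged ideal-geometry table so
#' that the built side chain reproduces the requested chi dihedrals exactly.
#'
#' @param backbone named list or data frame providing N, CA and C
#'   coordinates (rows named or a `name` column).
#' @param res_type 3-letter residue code.
#' @param chi_values numeric chi angles in degrees; length must match the
#'   residue type (`length 0` for Gly/Ala).
#' @return data frame with columns `name`, `element`, `x`, `y`, `z` of the
#'   side-chain heavy atoms including CB (empty for Gly).
#' @export
build_side_chain <- function(backbone, res_type, chi_values = numeric(0)) {
  res_type <- toupper(res_type)
  if (!res_type %in% names(N_CHI)) stop("unknown residue type ", res_type)
  nchi <- N_CHI[[res_type]]
  if (res_type %in% c("GLY", "ALA") && length(chi_values) > 0L)
    stop(res_type, " takes no chi angles")
  if (!res_type %in% c("GLY", "ALA") && length(chi_values) != nchi)
    stop(sprintf("%s requires %d chi angle(s), got %d", res_type, nchi, length(chi_values)))
  bb <- backbone_coords(backbone)
  for (nm in c("N", "CA", "C"))
    if (is.null(bb[[nm]])) stop("missing backbone atom ", nm)
  if (res_type == "GLY")
    return(data.frame(name = character(0), element = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0)))
  pos <- list(CB = place_atom(bb$C, bb$N, bb$CA, 1.530, 110.4, 122.55))
  if (res_type != "ALA") {
    for (row in SC_TOPOLOGY[[res_type]]) {
      getp <- function(nm) if (!is.null(pos[[nm]])) pos[[nm]] else bb[[nm]]
      tors <- resolve_torsion(row$tors, chi_values)
      pos[[row$name]] <- place_atom(getp(row$a), getp(row$b), getp(row$c),
                                    row$len, row$ang, tors)
    }
  }
  nm <- names(pos)
  data.frame(name = nm,
             element = substr(gsub("[0-9]", "", nm), 1, 1),
             x = vapply(pos, `[`, 0, 1L),
             y = vapply(pos, `[`, 0, 2L),
             z = vapply(pos, `[`, 0, 3L),
             row.names = NULL, stringsAsFactors = FALSE)
}

backbone_coords <- function(backbone) {
  if (is.data.frame(backbone)) {
    out <- lapply(seq_len(nrow(backbone)),
                  function(i) c(backbone$x[i], backbone$y[i], backbone$z[i]))
    names(out) <- backbone$name
    return(out)
  }
  backbone
}

#' Measure the chi dihedrals of a residue
#'
#' @param atoms data frame with `name`, `x`, `y`, `z` covering backbone and
#'   side-chain atoms of one residue.
#' @param res_type 3-letter code.
#' @return numeric vector of chi angles, degrees in (-180, 180].
#' @export
measure_chi <- function(atoms, res_type) {
  res_type <- toupper(res_type)
  defs <- CHI_ATOMS[[res_type]]
  if (is.null(defs)) return(numeric(0))
  get <- function(nm) {
    i <- match(nm, atoms$name)
    if (is.na(i)) stop("missing atom ", nm, " for chi measurement")
    c(atoms$x[i], atoms$y[i], atoms$z[i])
  }
  vapply(defs, function(q) dihedral_angle(get(q[1]), get(q[2]), get(q[3]), get(q[4])), 0)
}
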