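# Conformational-heterogeneity and bookkeeping analyses: within-crystal
# B-factor Z-scores (comparable across crystals because Z-scores are
# invariant to the affine offsets that crystalline disorder adds to raw
# B-factors), mutation-set accounting, and catalytic efficiency (kcat/KM)
# from the sub-saturating linear regime of the Michaelis-Menten model.

#' B-factor Z-scores of a structure
#'
#' Computes `z_i = (B_i - mean B)/sd B` over the chosen atom population
#' (population standard deviation; highest-occupancy conformer atoms of
#' standard residues only) and per-residue mean Z-scores over side-chain
#' heavy atoms. Positive Z-scores indicate above-average flexibility,
#' negative ones rigidity, relative to the average residue of the same
#' crystal.
#'
#' @param model a `structure_model`.
#' @param population `"sidechain"` (default; side-chain heavy atoms, CB
#'   included) or `"all"` (all heavy atoms).
#' @return a `bfactor_report`: per-atom table (`z`), per-residue table
#'   (`mean_z`; Gly and residues with no side-chain atoms excluded rather
#'   than zero-filled in sidechain mode), and the population mean/sd used.
#' @export
bfactor_zscores <- function(model, population = c("sidechain", "all")) {
  population <- match.arg(population)
  a <- apply_policy(model$atoms, conformer_policy())
  a <- a[!a$is_h & a$res_type %in% names(N_CHI), , drop = FALSE]
  if (population == "sidechain")
    a <- a[!a$name %in% BACKBONE_ATOMS, , drop = FALSE]
  if (nrow(a) < 2L) stop("fewer than 2 atoms in the Z-score population")
  mu <- mean(a$b)
  sigma <- sqrt(mean((a$b - mu)^2))  # population sd
  if (sigma < 1e-12)
    stop("degenerate population: B-factor standard deviation is zero")
  a$z <- (a$b - mu) / sigma
  atoms <- a[, c("chain", "resno", "ins", "res_type", "name", "b", "z")]
  per_res <- atoms[!(atoms$name %in% BACKBONE_ATOMS), , drop = FALSE]
  if (nrow(per_res) > 0L) {
    key <- paste(per_res$chain, per_res$resno, per_res$ins, sep = "|")
    agg <- do.call(rbind, lapply(split(seq_len(nrow(per_res)), key), function(i) {
      data.frame(chain = per_res$chain[i[1L]], resno = per_res$resno[i[1L]],
                 ins = per_res$ins[i[1L]], res_type = per_res$res_type[i[1L]],
                 mean_z = mean(per_res$z[i]), n_atoms = length(i),
                 stringsAsFactors = FALSE)
    }))
    agg <- agg[order(agg$chain, agg$resno, agg$ins), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(chain = character(0), resno = integer(0),
                      ins = character(0), res_type = character(0),
                      mean_z = numeric(0), n_atoms = integer(0))
  }
  structure(list(atoms = atoms, residues = agg, mean_b = mu, sd_b = sigma,
                 population = population),
            class = "bfactor_report")
}

#' @export
print.bfactor_report <- function(x, ...) {
  cat(sprintf("<bfactor_report> population %s: %d atoms, mean B %.2f, sd B %.2f; %d residues\n",
              x$population, nrow(x$atoms), x$mean_b, x$sd_b, nrow(x$residues)))
  invisible(x)
}

#' Average per-residue Z-scores across chains
#'
#' Residues present in several chains get the arithmetic mean of their
#' per-chain mean Z-scores; residues found in a single chain pass through
#' with `single_chain = TRUE`.
#'
#' @param report a `bfactor_report`.
#' @return data frame with `resno`, `ins`, `res_type`, `mean_z`, `n_chains`,
#'   `single_chain`.
#' @export
average_over_chains <- function(report) {
  r <- report$residues
  if (nrow(r) == 0L) return(data.frame())
  key <- paste(r$resno, r$ins, sep = "|")
  out <- do.call(rbind, lapply(split(seq_len(nrow(r)), key), function(i) {
    data.frame(resno = r$resno[i[1L]], ins = r$ins[i[1L]],
               res_type = r$res_type[i[1L]],
               mean_z = mean(r$mean_z[i]), n_chains = length(i),
               single_chain = length(i) == 1L, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$resno, out$ins), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse mutation tokens
#'
#' Tokens follow the `K50Q` convention (wild-type letter, position, new
#' letter). Positions must be unique within a set.
#'
#' @param text whitespace-separated token string or character vector.
#' @param design_sites optional annotation source: a character vector of
#'   tokens, or integer positions, flagged `design_site = TRUE` (e.g. sites
#'   optimized during an earlier design round).
#' @return a `mutation_set`.
#' @export
parse_mutations <- function(text, design_sites = NULL) {
  tokens <- unlist(strsplit(paste(text, collapse = " "), "[[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    return(structure(list(tokens = data.frame(
      wt = character(0), pos = integer(0), mut = character(0),
      token = character(0), design_site = logical(0))),
      class = "mutation_set"))
  }
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", tokens)
  if (any(!ok)) stop("malformed mutation token(s): ",
                     paste(tokens[!ok], collapse = ", "))
  wt <- substr(tokens, 1, 1)
  mut <- substring(tokens, nchar(tokens))
  pos <- as.integer(gsub("[A-Z]", "", tokens))
  bad <- !(wt %in% names(AA3)) | !(mut %in% names(AA3))
  if (any(bad)) stop("invalid amino-acid letter in token(s): ",
                     paste(tokens[bad], collapse = ", "))
  if (anyDuplicated(pos))
    stop("duplicate position(s) in mutation set: ",
         paste(unique(pos[duplicated(pos)]), collapse = ", "))
  flag <- if (is.null(design_sites)) rep(FALSE, length(tokens))
          else if (is.numeric(design_sites)) pos %in% design_sites
          else tokens %in% design_sites
  structure(list(tokens = data.frame(wt = wt, pos = pos, mut = mut,
                                     token = tokens, design_site = flag,
                                     stringsAsFactors = FALSE)),
            class = "mutation_set")
}

#' @export
print.mutation_set <- function(x, ...) {
  cat(sprintf("<mutation_set> %d mutation(s): %s\n", nrow(x$tokens),
              paste(x$tokens$token, collapse = " ")))
  invisible(x)
}

#' @export
length.mutation_set <- function(x) nrow(x$tokens)

#' Format a mutation set back to its token string
#' @param set a `mutation_set`.
#' @return single space-separated string (round-trips with
#'   [parse_mutations()]).
#' @export
format_mutations <- function(set) paste(set$tokens$token, collapse = " ")

#' Set difference of mutation sets (exact token match)
#'
#' @param a,b `mutation_set`s.
#' @return mutation set with the tokens of `a` not present in `b`.
#' @export
mutation_set_difference <- function(a, b) {
  keep <- !(a$tokens$token %in% b$tokens$token)
  structure(list(tokens = a$tokens[keep, , drop = FALSE]),
            class = "mutation_set")
}

#' Count annotated tokens
#' @param set a `mutation_set`.
#' @param flag annotation column (default `"design_site"`).
#' @return integer count of flagged tokens.
#' @export
count_annotated <- function(set, flag = "design_site") {
  if (!flag %in% names(set$tokens)) stop("no annotation column '", flag, "'")
  sum(set$tokens[[flag]])
}

#' Catalytic efficiency from the linear Michaelis-Menten regime
#'
#' In the sub-saturating regime (`[S] << K_M`) initial rates follow
#' `v0 = (kcat/KM) [E0] [S]`; the efficiency is the least-squares slope of
#' `v0` against `[E0][S]`, constrained through the origin (the model has no
#' intercept). The regression standard error of the slope is reported.
#'
#' @param data data frame (or `kinetics_data`) with columns
#'   `substrate_conc` (M), `initial_rate` (M/s) and `enzyme_conc` (M,
#'   constant within the dataset).
#' @param origin constrain the fit through the origin (default `TRUE`).
#' @return an `efficiency_estimate` with `kcat_over_km` (1/(M s)) and
#'   `fit_error`.
#' @export
fit_efficiency <- function(data, origin = TRUE) {
  stopifnot(all(c("substrate_conc", "initial_rate", "enzyme_conc") %in% names(data)))
  if (nrow(data) < 2L) stop("need at least 2 kinetic data points")
  if (length(unique(data$substrate_conc)) < 2L)
    stop("degenerate design: a single substrate concentration")
  if (length(unique(data$enzyme_conc)) != 1L)
    stop("enzyme concentration must be constant within a dataset")
  if (any(data$substrate_conc <= 0) || any(data$enzyme_conc <= 0))
    stop("concentrations must be positive")
  x <- data$enzyme_conc * data$substrate_conc
  y <- data$initial_rate
  fit <- if (origin) lm(y ~ 0 + x) else lm(y ~ x)
  # noiseless data triggers a harmless "essentially perfect fit" warning
  cf <- suppressWarnings(summary(fit))$coefficients
  slope_row <- if (origin) 1L else 2L
  est <- unname(cf[slope_row, "Estimate"])
  se <- unname(cf[slope_row, "Std. Error"])
  if (!is.finite(se)) se <- 0
  structure(list(kcat_over_km = est, fit_error = se, n = nrow(data),
                 origin = origin),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("<efficiency_estimate> kcat/KM = %.4g +/- %.2g 1/(M s) (n = %d)\n",
              x$kcat_over_km, x$fit_error, x$n))
  invisible(x)
}

#' Fold change between two catalytic efficiencies
#' @param eff_a,eff_b efficiencies (1/(M s)) or `efficiency_estimate`s.
#' @return dimensionless ratio `eff_a / eff_b`.
#' @export
fold_change <- function(eff_a, eff_b) {
  val <- function(e) if (inherits(e, "efficiency_estimate")) e$kcat_over_km else e
  a <- val(eff_a); b <- val(eff_b)
  if (b <= 0) stop("denominator efficiency must be > 0")
  a / b
}

#' Kemp eliminase variant table (mutations and printed efficiencies)
#'
#' The published variant table of the HG-series Kemp eliminases: mutation
#' tokens relative to HG3, the subset at sites optimized during the original
#' computational design round, and the reported catalytic efficiencies.
#'
#' @return data frame with columns `variant`, `mutations`, `design_sites`,
#'   `kcat_km`, `kcat_km_err`.
#' @export
hg_series_mutations <- function() {
  path <- system.file("extdata", "hg_series_kinetics.tsv", package = "ensrepack")
  read.delim(path, stringsAsFactors = FALSE)
}
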