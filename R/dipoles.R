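EA_TO_DEBYE <- 4.803205  # 1 e*Angstrom in Debye

#' Build a charge set for a structure
#'
#' Per-atom partial charges (e) keyed by residue index and atom name, e.g.
#' Hirshfeld charges imported from a population analysis. Every referenced
#' atom must exist in the structure.
#'
#' @param structure A `peptide_structure`.
#' @param charges Data frame with columns `residue_index`, `atom`, `charge`.
#' @param provenance Free-text label (e.g. `"Hirshfeld"`, `"synthetic"`).
#' @return Object of class `charge_set`.
#' @export
charge_set <- function(structure, charges, provenance = "unspecified") {
  stopifnot(inherits(structure, "peptide_structure"))
  need <- c("residue_index", "atom", "charge")
  if (!is.data.frame(charges) || !all(need %in% names(charges))) {
    stop("helixhb: charges must be a data frame with residue_index, atom, charge",
         call. = FALSE)
  }
  for (i in seq_len(nrow(charges))) {
    if (!has_atom(structure, charges$residue_index[i], charges$atom[i])) {
      stop(sprintf("helixhb: charge refers to missing atom %s in residue %d",
                   charges$atom[i], charges$residue_index[i]), call. = FALSE)
    }
  }
  structure(list(structure = structure, charges = charges, provenance = provenance),
            class = "charge_set")
}

#' Read a charge table from a TSV file
#'
#' Columns `residue`, `atom`, `charge` (tab separated, with header).
#'
#' @param structure The `peptide_structure` the charges belong to.
#' @param path File path.
#' @param provenance Label recorded on the resulting set.
#' @return A `charge_set`.
#' @export
read_charges <- function(structure, path, provenance = basename(path)) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("residue", "atom", "charge") %in% names(tab))) {
    stop("helixhb: charge file must have columns residue, atom, charge", call. = FALSE)
  }
  charge_set(structure,
             data.frame(residue_index = tab$residue, atom = tab$atom,
                        charge = tab$charge, stringsAsFactors = FALSE),
             provenance)
}

get_charge <- function(cs, residue_index, atom) {
  sel <- cs$charges$residue_index == residue_index & cs$charges$atom == atom
  if (sum(sel) != 1) {
    stop(sprintf("helixhb: missing charge for atom %s in residue %d", atom,
                 residue_index), call. = FALSE)
  }
  cs$charges$charge[sel]
}

#' Local two-point dipole moment of a C=O or N-H group
#'
#' The bond dipole assigned to a backbone group from its two atomic
#' charges: `mu = 1/2 (q_first - q_second) (r_first - r_second)`, with
#' (first, second) = (C, O) for the carbonyl and (H, N) for the amide
#' group, converted from e*Angstrom to Debye (factor 4.803205). Depends
#' only on the charge difference and the bond vector, so it is invariant
#' under rigid translation and rotates covariantly.
#'
#' @param structure A `peptide_structure`.
#' @param charges A `charge_set` on the same structure.
#' @param group `"CO"` or `"NH"`.
#' @param residue_index Residue owning the group.
#' @return List of class `local_dipole` with `group`, `residue_index`,
#'   `vector` (Debye, 3-vector) and `norm` (Debye).
#' @examples
#' wh <- build_helix("310", 2)
#' cs <- charge_set(wh, data.frame(residue_index = c(0, 0), atom = c("C", "O"),
#'                                 charge = c(0.2, -0.3)), "illustrative")
#' local_group_dipole(wh, cs, "CO", 0)$norm
#' @export
local_group_dipole <- function(structure, charges, group = c("CO", "NH"),
                               residue_index) {
  group <- match.arg(group)
  stopifnot(inherits(charges, "charge_set"))
  atoms <- if (group == "CO") c("C", "O") else c("H", "N")
  r1 <- atom_xyz(structure, residue_index, atoms[1])
  r2 <- atom_xyz(structure, residue_index, atoms[2])
  q1 <- get_charge(charges, residue_index, atoms[1])
  q2 <- get_charge(charges, residue_index, atoms[2])
  vec <- 0.5 * (q1 - q2) * (r1 - r2) * EA_TO_DEBYE
  structure(list(group = group, residue_index = residue_index,
                 vector = vec, norm = vnorm(vec)),
            class = "local_dipole")
}

#' @export
print.local_dipole <- function(x, ...) {
  cat(sprintf("<local_dipole> %s group of residue %d: |mu| = %.4f D\n",
              x$group, x$residue_index, x$norm))
  invisible(x)
}

#' Per-pair dipole-norm table with model averages and model ratios
#'
#' Arranges per-pair dipole norms of several model systems (rows) into a
#' table with a per-model `Average` column (arithmetic mean over pairs)
#' and, for each requested model pair, a ratio row. Ratio rows hold the
#' per-pair ratio for each pair; their `Average` cell is the mean of the
#' per-pair ratios (`mode = "mean_of_ratios"`, the canonical convention
#' here) or the ratio of the two model averages
#' (`mode = "ratio_of_means"`); the two conventions can differ in the
#' fourth decimal.
#'
#' @param norms Matrix or data frame: rows = models, columns = pairs, cell
#'   = dipole norm in Debye. Row and column names required.
#' @param ratios List of length-2 character vectors
#'   `c(numerator_model, denominator_model)`; defaults to every other
#'   model over `"MH"` when an MH row exists.
#' @param mode Convention for the ratio rows' `Average` cell.
#' @return Data frame with the pair columns plus `Average`; model rows
#'   first, then `Ratio (num/den)` rows. Values are unrounded; round to 4
#'   decimals for display.
#' @export
dipole_ratio_table <- function(norms, ratios = NULL,
                               mode = c("mean_of_ratios", "ratio_of_means")) {
  mode <- match.arg(mode)
  norms <- as.matrix(norms)
  if (is.null(rownames(norms)) || is.null(colnames(norms))) {
    stop("helixhb: norms need model row names and pair column names", call. = FALSE)
  }
  if (is.null(ratios)) {
    ratios <- if ("MH" %in% rownames(norms)) {
      lapply(setdiff(rownames(norms), "MH"), function(m) c(m, "MH"))
    } else list()
  }
  out <- data.frame(norms, check.names = FALSE)
  out$Average <- rowMeans(norms)
  for (rt in ratios) {
    num <- rt[1]; den <- rt[2]
    if (!num %in% rownames(norms) || !den %in% rownames(norms)) {
      stop("helixhb: ratio refers to unknown model row: ", num, "/", den, call. = FALSE)
    }
    if (any(norms[den, ] == 0)) {
      bad <- colnames(norms)[norms[den, ] == 0][1]
      stop(sprintf("helixhb: zero denominator dipole for pair %s in model %s",
                   bad, den), call. = FALSE)
    }
    rr <- norms[num, ] / norms[den, ]
    avg <- if (mode == "mean_of_ratios") mean(rr) else
      mean(norms[num, ]) / mean(norms[den, ])
    out[sprintf("Ratio (%s/%s)", num, den), ] <- c(rr, avg)
  }
  out
}
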