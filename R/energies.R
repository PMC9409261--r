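HARTREE_TO_KCAL <- 627.5094740631

#' Combine fragment energies with the negative fragmentation formula
#'
#' The hydrogen-bond energy is extracted from four total energies as
#' `E_HB = E_sys - E_minusA - E_minusD + E_minusAD`: the entire system,
#' the system lacking the acceptor C=O, the system lacking the donor N-H,
#' and the system lacking both. For any pairwise-additive energy model the
#' combination isolates exactly the acceptor-donor cross interaction; for
#' a quantum-chemical backend it additionally captures the many-body
#' redistribution terms. The formula is invariant under a uniform shift of
#' all four energies and linear in each argument.
#'
#' @param e_sys,e_minus_A,e_minus_D,e_minus_AD Energies in kcal/mol
#'   (vectorized). Alternatively pass a single list/one-row data frame with
#'   these fields as `e_sys`.
#' @return Hydrogen-bond energy in kcal/mol.
#' @examples
#' nfa_combine(-100.5, -60.2, -45.3, -5.2)  # -0.2
#' @export
nfa_combine <- function(e_sys, e_minus_A, e_minus_D, e_minus_AD) {
  if (missing(e_minus_A) && (is.list(e_sys) || is.data.frame(e_sys))) {
    rec <- e_sys
    e_minus_A <- rec$e_minus_A; e_minus_D <- rec$e_minus_D
    e_minus_AD <- rec$e_minus_AD; e_sys <- rec$e_sys
  }
  vals <- cbind(e_sys, e_minus_A, e_minus_D, e_minus_AD)
  if (any(!is.finite(vals))) {
    stop("helixhb: all four fragment energies must be finite", call. = FALSE)
  }
  as.numeric(((e_sys - e_minus_A) - e_minus_D) + e_minus_AD)
}

#' Embedded ff99SB-style nonbonded parameters for the peptide group
#'
#' Partial charges (e) and Lennard-Jones parameters (rmin/2 in Angstrom,
#' epsilon in kcal/mol) for the backbone peptide-group atoms C, O, N, H of
#' alanine and the Ace/Nme caps, following the published AMBER ff99SB
#' values, plus the AMBER electrostatic constant (332.0522173
#' kcal*A/(mol*e^2)). Atoms outside these four roles (alpha/methyl carbons
#' and their hydrogens) carry no parameters in this hydrogen-bond-focused
#' energy model.
#'
#' @param coulomb_constant Override for the electrostatic constant.
#' @return A list of class `forcefield_params` with `charges` (per residue
#'   role), `rmin2`, `epsilon`, `coulomb`.
#' @export
forcefield_params <- function(coulomb_constant = 332.0522173) {
  structure(list(
    charges = list(
      ALA = c(N = -0.4157, H = 0.2719, C = 0.5973, O = -0.5679),
      ACE = c(C = 0.5972, O = -0.5679),
      NME = c(N = -0.4157, H = 0.2719)
    ),
    rmin2 = c(C = 1.9080, O = 1.6612, N = 1.8240, H = 0.6000),
    epsilon = c(C = 0.0860, O = 0.2100, N = 0.1700, H = 0.0157),
    coulomb = coulomb_constant
  ), class = "forcefield_params")
}

# Per-atom parameter assignment: only backbone C, O, N, H (amide) carry
# charges/LJ; everything else (CA, CB, CH3, aliphatic H, cap HX) is inert.
atom_ff_roles <- function(atoms, ff) {
  role <- rep(NA_character_, nrow(atoms))
  role[atoms$name == "C"] <- "C"
  role[atoms$name == "O"] <- "O"
  role[atoms$name == "N"] <- "N"
  role[atoms$name == "H"] <- "H"
  q <- rep(0, nrow(atoms))
  for (i in which(!is.na(role))) {
    rn <- atoms$residue_name[i]
    qs <- ff$charges[[rn]]
    if (is.null(qs)) qs <- ff$charges$ALA
    qi <- qs[role[i]]
    q[i] <- if (is.na(qi)) ff$charges$ALA[role[i]] else qi
  }
  list(role = role, q = q)
}

lj_bc <- function(ff, ri, rj) {
  rmin <- unname(ff$rmin2[ri] + ff$rmin2[rj])
  eps <- unname(sqrt(ff$epsilon[ri] * ff$epsilon[rj]))
  c(B = eps * rmin^12, C = 2 * eps * rmin^6)
}

pairwise_energy <- function(xyz_i, q_i, role_i, xyz_j, q_j, role_j, ff) {
  r <- vnorm(xyz_i - xyz_j)
  if (r < 1e-8) stop("helixhb: degenerate geometry, coincident atoms in energy evaluation",
                     call. = FALSE)
  e <- ff$coulomb * q_i * q_j / r
  if (!is.na(role_i) && !is.na(role_j)) {
    bc <- lj_bc(ff, role_i, role_j)
    e <- e + bc["B"] / r^12 - bc["C"] / r^6
  }
  unname(e)
}

#' Molecular-mechanics hydrogen-bond energy of one pair
#'
#' The point-charge plus Lennard-Jones interaction energy between the
#' acceptor peptide group (C, O of the acceptor residue and N, H of the
#' following residue) and the donor peptide group (C, O of the preceding
#' residue and N, H of the donor residue): the 4 x 4 = 16 cross pairs, with
#' no intra-group terms, no cutoff, and no 1-4 scaling (the two groups are
#' at least five covalent bonds apart in every model considered).
#'
#' @param structure A `peptide_structure`.
#' @param pair One row from [detect_hbond_pairs()] (or a model's
#'   `target_pair`).
#' @param ff [forcefield_params()].
#' @return Energy in kcal/mol.
#' @export
mm_pair_energy <- function(structure, pair, ff = forcefield_params()) {
  pair <- pair_row(pair)
  a <- pair$acceptor_res
  d <- pair$donor_res
  grp <- function(res_co, res_nh) {
    list(C = list(res_co, "C"), O = list(res_co, "O"),
         N = list(res_nh, "N"), H = list(res_nh, "H"))
  }
  acc <- grp(a, a + 1)
  don <- grp(d - 1, d)
  roles <- c("C", "O", "N", "H")
  rn_of <- function(res) structure$atoms$residue_name[structure$atoms$residue_index == res][1]
  e <- 0
  for (ri in roles) {
    sel_i <- acc[[ri]]
    xyz_i <- atom_xyz(structure, sel_i[[1]], sel_i[[2]])
    q_i <- charge_for(ff, rn_of(sel_i[[1]]), ri)
    for (rj in roles) {
      sel_j <- don[[rj]]
      xyz_j <- atom_xyz(structure, sel_j[[1]], sel_j[[2]])
      q_j <- charge_for(ff, rn_of(sel_j[[1]]), rj)
      e <- e + pairwise_energy(xyz_i, q_i, ri, xyz_j, q_j, rj, ff)
    }
  }
  e
}

charge_for <- function(ff, residue_name, role) {
  qs <- ff$charges[[residue_name]]
  if (is.null(qs) || is.na(qs[role])) qs <- ff$charges$ALA
  unname(qs[role])
}

#' Molecular-mechanics energy backend for the NFA pipeline
#'
#' Returns an `evaluate(structure) -> energy` closure summing Coulomb and
#' Lennard-Jones terms over all pairs of parameterized peptide-group atoms
#' (backbone C, O, N, amide H), excluding pairs within the same peptide
#' unit (the C=O of residue i with the N-H of residue i+1), whose
#' geometry is fixed by covalent bonding. Like a quantum-chemical total
#' energy, the absolute value is not meaningful on its own; NFA
#' combinations of it are. The closure is deterministic: identical
#' structures give bitwise-identical energies.
#'
#' @param ff [forcefield_params()].
#' @return A function of one `peptide_structure` argument returning
#'   kcal/mol.
#' @export
mm_backend <- function(ff = forcefield_params()) {
  force(ff)
  function(structure) {
    stopifnot(inherits(structure, "peptide_structure"))
    atoms <- structure$atoms
    par <- atom_ff_roles(atoms, ff)
    keep <- which(!is.na(par$role))
    if (length(keep) < 2) return(0)
    xyz <- as.matrix(atoms[keep, c("x", "y", "z")])
    role <- par$role[keep]
    q <- par$q[keep]
    # peptide-unit id: C/O of residue i belong to unit i, N/H to unit i-1
    unit <- ifelse(role %in% c("C", "O"), atoms$residue_index[keep],
                   atoms$residue_index[keep] - 1L)
    e <- 0
    n <- length(keep)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (unit[i] == unit[j]) next
        e <- e + pairwise_energy(xyz[i, ], q[i], role[i], xyz[j, ], q[j], role[j], ff)
      }
    }
    e
  }
}

#' Read a table of externally computed fragment energies
#'
#' Expects delimited text (TSV by default) with header columns `model`,
#' `fragment`, `energy`, `unit`; `fragment` must be one of `sys`,
#' `minusA`, `minusD`, `minusAD` and every model must have all four rows
#' exactly once. Energies are converted to kcal/mol (`hartree` values by
#' the factor 627.5094740631).
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return Data frame with one row per model and columns `model`, `e_sys`,
#'   `e_minus_A`, `e_minus_D`, `e_minus_AD` (kcal/mol).
#' @export
load_energy_table <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("model", "fragment", "energy", "unit")
  if (!all(need %in% names(tab))) {
    stop("helixhb: energy table must have columns model, fragment, energy, unit",
         call. = FALSE)
  }
  valid_frag <- c("sys", "minusA", "minusD", "minusAD")
  bad <- setdiff(unique(tab$fragment), valid_frag)
  if (length(bad)) {
    stop("helixhb: unknown fragment role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  conv <- function(e, unit) {
    switch(unit,
           hartree = e * HARTREE_TO_KCAL,
           `kcal/mol` = e,
           kcal = e,
           stop("helixhb: unknown energy unit: ", unit, call. = FALSE))
  }
  tab$kcal <- mapply(conv, tab$energy, tab$unit)
  if (anyDuplicated(tab[, c("model", "fragment")])) {
    dup <- tab[duplicated(tab[, c("model", "fragment")]), ]
    stop("helixhb: duplicate (model, fragment) rows, first: ",
         dup$model[1], "/", dup$fragment[1], call. = FALSE)
  }
  out <- lapply(split(tab, tab$model), function(m) {
    missing_frag <- setdiff(valid_frag, m$fragment)
    if (length(missing_frag)) {
      stop("helixhb: incomplete record for model ", m$model[1], ": missing ",
           paste(missing_frag, collapse = ", "), call. = FALSE)
    }
    e <- stats::setNames(m$kcal, m$fragment)
    data.frame(model = m$model[1], e_sys = e["sys"], e_minus_A = e["minusA"],
               e_minus_D = e["minusD"], e_minus_AD = e["minusAD"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-pair, per-model hydrogen-bond energies through the NFA
#'
#' For every backbone hydrogen-bond pair of a whole-helix model and every
#' requested model kind, derives the model structure ([extract_model()]),
#' builds the four NFA fragments ([make_nfa_fragments()]), evaluates the
#' energy backend on each, and combines them with [nfa_combine()].
#'
#' @param wh The parent whole-helix `peptide_structure`.
#' @param kinds Character vector of model kinds (see [extract_model()]).
#' @param backend An `evaluate(structure) -> kcal/mol` function, e.g.
#'   [mm_backend()].
#' @param offset Hydrogen-bond residue offset (3 or 4).
#' @return Data frame: `model`, `pair`, `kind`, `class`,
#'   `adjacent_to_terminal`, `e_hb` (kcal/mol). Zero rows if `kinds` is
#'   empty.
#' @export
hbond_energy_pipeline <- function(wh, kinds, backend, offset = 3) {
  pairs <- classify_pair_position(detect_hbond_pairs(wh, offset))
  rows <- list()
  for (kind in kinds) {
    for (i in seq_len(nrow(pairs))) {
      model <- extract_model(wh, pairs[i, ], kind)
      frags <- make_nfa_fragments(model)
      e <- nfa_combine(backend(frags$sys), backend(frags$minus_A),
                       backend(frags$minus_D), backend(frags$minus_AD))
      rows[[length(rows) + 1]] <- data.frame(
        model = wh$label, pair = pairs$label[i], kind = kind,
        class = pairs$class[i], adjacent_to_terminal = pairs$adjacent_to_terminal[i],
        e_hb = e, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(model = character(0), pair = character(0), kind = character(0),
                      class = character(0), adjacent_to_terminal = logical(0),
                      e_hb = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Peptide-group MM energies for every pair of a helix model
#'
#' @inheritParams hbond_energy_pipeline
#' @param ff [forcefield_params()].
#' @return Data frame with `model`, `pair`, `class`, `adjacent_to_terminal`,
#'   `e_mm` (kcal/mol).
#' @export
mm_hbond_energies <- function(wh, offset = 3, ff = forcefield_params()) {
  pairs <- classify_pair_position(detect_hbond_pairs(wh, offset))
  pairs$e_mm <- vapply(seq_len(nrow(pairs)),
                       function(i) mm_pair_energy(wh, pairs[i, ], ff), numeric(1))
  data.frame(model = wh$label, pair = pairs$label, class = pairs$class,
             adjacent_to_terminal = pairs$adjacent_to_terminal, e_mm = pairs$e_mm,
             stringsAsFactors = FALSE)
}
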