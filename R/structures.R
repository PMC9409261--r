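#' Ideal internal-geometry parameters for peptide construction
#'
#' Returns the bond lengths (Angstrom) and bond angles (degrees) used by
#' [build_capped_polyalanine()]. Values follow standard peptide geometry
#' libraries (Engh--Huber-style averages); they stand in for quantum-
#' mechanically relaxed internal coordinates, which are conformation
#' dependent and not tabulated here. All values can be overridden, so the
#' whole geometry model is swappable in one place.
#'
#' @param ... Named overrides for any of the default entries.
#' @return A named list of class `geometry_params`.
#' @examples
#' p <- geometry_params(b_c_o = 1.229)
#' p$b_c_o
#' @export
geometry_params <- function(...) {
  p <- list(
    # bond lengths (Angstrom)
    b_n_ca  = 1.458,  # N-CA
    b_ca_c  = 1.525,  # CA-C'
    b_c_n   = 1.329,  # C'-N peptide bond
    b_c_o   = 1.231,  # C'=O
    b_n_h   = 1.010,  # amide N-H
    b_ca_cb = 1.521,  # CA-CB
    b_c_h   = 1.090,  # aliphatic C-H (methyl, HA, HB)
    # backbone bond angles (degrees)
    a_c_n_ca = 121.7, # C'(i-1)-N-CA
    a_n_ca_c = 111.2, # N-CA-C' (tau)
    a_ca_c_n = 116.2, # CA-C'-N(i+1)
    a_o_c_n  = 123.0, # O=C'-N(i+1)
    a_c_n_h  = 119.1, # C'(i-1)-N-H
    # side-chain / cap angles (degrees)
    a_n_ca_cb = 110.4,
    a_n_ca_ha = 108.5,
    a_x_c_h   = 109.5, # tetrahedral H on methyl / CB carbons
    # substituent torsions about the N-CA axis, offsets from C' (degrees);
    # -122.5 for CB gives L-alanine
    t_cb_offset = -122.5,
    t_ha_offset = 118.9,
    omega = 180
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      stop("helixhb: unknown geometry parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    p[names(over)] <- over
  }
  validate_geometry_params(p)
  structure(p, class = "geometry_params")
}

validate_geometry_params <- function(p) {
  lens <- unlist(p[startsWith(names(p), "b_")])
  angs <- unlist(p[startsWith(names(p), "a_")])
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("helixhb: invalid geometry parameters, all bond lengths must be positive",
         call. = FALSE)
  }
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs >= 180)) {
    stop("helixhb: invalid geometry parameters, bond angles must lie in (0, 180) degrees",
         call. = FALSE)
  }
  invisible(p)
}

new_peptide_structure <- function(atoms, n_ala, phi = NA_real_, psi = NA_real_,
                                  omega = NA_real_, label = "") {
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, n_ala = n_ala, phi = phi, psi = psi,
         omega = omega, label = label),
    class = "peptide_structure"
  )
}

#' @export
print.peptide_structure <- function(x, ...) {
  cat(sprintf("<peptide_structure> %s: %d atoms, %d residues (n_ala = %d)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$atoms), length(unique(x$atoms$residue_index)), x$n_ala))
  if (is.finite(x$phi)) {
    cat(sprintf("  construction targets: phi = %g, psi = %g, omega = %g deg\n",
                x$phi, x$psi, x$omega))
  }
  invisible(x)
}

atom_xyz <- function(structure, residue_index, name) {
  a <- structure$atoms
  i <- which(a$residue_index == residue_index & a$name == name)
  if (length(i) != 1) {
    stop(sprintf("helixhb: missing atom %s in residue %d%s", name, residue_index,
                 if (nzchar(structure$label)) paste0(" of ", structure$label) else ""),
         call. = FALSE)
  }
  c(a$x[i], a$y[i], a$z[i])
}

has_atom <- function(structure, residue_index, name) {
  a <- structure$atoms
  any(a$residue_index == residue_index & a$name == name)
}

element_from_name <- function(name) {
  substr(gsub("^[0-9]+", "", name), 1, 1)
}

#' Build a capped polyalanine helix at fixed backbone dihedrals
#'
#' Constructs Ace-(Ala)n-Nme with every residue at the requested
#' `(phi, psi)` and planar trans peptide bonds (`omega` from `params`),
#' using ideal internal geometry and the NeRF chain-extension algorithm.
#' The acetyl cap occupies residue index 0 (contributing a C=O acceptor)
#' and the N-methyl amide cap occupies index `n_ala + 1` (contributing an
#' N-H donor), so both caps participate in the backbone hydrogen-bond
#' network. Alanines are built as L-enantiomers.
#'
#' @param n_ala Number of alanine residues (>= 1).
#' @param phi,psi Backbone dihedral targets in degrees, applied to every
#'   alanine. `-49, -26` gives a 3_10-helix; `-57, -47` an alpha-helix.
#' @param params A [geometry_params()] list.
#' @param label Optional model label; defaults to `WH_<n_ala>`.
#' @return A `peptide_structure` with `6 + 10 * n_ala + 6` atoms.
#' @examples
#' wh <- build_capped_polyalanine(4, -49, -26)
#' nrow(wh$atoms)  # 52
#' @export
build_capped_polyalanine <- function(n_ala, phi, psi, params = geometry_params(),
                                     label = NULL) {
  if (!is.numeric(n_ala) || length(n_ala) != 1 || n_ala < 1 || n_ala != round(n_ala)) {
    stop("helixhb: n_ala must be a single integer >= 1", call. = FALSE)
  }
  n_ala <- as.integer(n_ala)
  if (!inherits(params, "geometry_params")) validate_geometry_params(params)
  p <- params
  omega <- p$omega
  if (is.null(label)) label <- sprintf("WH_%d", n_ala)

  nres <- n_ala + 2
  pos <- list()  # pos[[res]][[name]] -> 3-vector (1-based residue = index 0)
  setp <- function(res, name, xyz) {
    key <- as.character(res)
    cur <- pos[[key]]
    if (is.null(cur)) cur <- list()
    cur[[name]] <- xyz
    pos[[key]] <<- cur
  }
  getp <- function(res, name) pos[[as.character(res)]][[name]]

  ## --- main chain: CH3(0) - C(0) - [N CA C](1..n) - N(n+1) - CH3(n+1) ---
  setp(0, "CH3", c(0, 0, 0))
  setp(0, "C", c(p$b_ca_c, 0, 0))
  # N(1) in the xy-plane at the CH3-C-N angle
  ang <- p$a_ca_c_n * DEG2RAD
  setp(1, "N", getp(0, "C") + p$b_c_n * c(-cos(ang), sin(ang), 0))

  prev2 <- getp(0, "CH3"); prev1 <- getp(0, "C"); prev0 <- getp(1, "N")
  extend <- function(bond, ang, tor) {
    newp <- place_atom(prev2, prev1, prev0, bond, ang, tor)
    prev2 <<- prev1; prev1 <<- prev0; prev0 <<- newp
    newp
  }
  for (i in seq_len(n_ala)) {
    setp(i, "CA", extend(p$b_n_ca, p$a_c_n_ca, omega))       # omega(i-1, i)
    setp(i, "C",  extend(p$b_ca_c, p$a_n_ca_c, phi))         # phi(i)
    nxt <- extend(p$b_c_n, p$a_ca_c_n, psi)                  # psi(i)
    setp(i + 1, "N", nxt)
  }
  setp(nres - 1, "CH3", extend(p$b_n_ca, p$a_c_n_ca, omega))

  ## --- carbonyl oxygens: O(i) on C(i), cis to CA/CH3 of residue i+1 ---
  for (i in 0:(n_ala)) {
    ref <- if (i + 1 == nres - 1) getp(i + 1, "CH3") else getp(i + 1, "CA")
    setp(i, "O", place_atom(ref, getp(i + 1, "N"), getp(i, "C"),
                            p$b_c_o, p$a_o_c_n, 0))
  }
  ## --- amide hydrogens: H(i) on N(i), trans to O(i-1) ---
  for (i in seq_len(nres - 1)) {
    setp(i, "H", place_atom(getp(i - 1, "O"), getp(i - 1, "C"), getp(i, "N"),
                            p$b_n_h, p$a_c_n_h, 180))
  }
  ## --- alanine side chains: CB, HA about the N-CA axis, HB methyl ---
  for (i in seq_len(n_ala)) {
    cprev <- if (i == 1) getp(0, "C") else getp(i - 1, "C")
    n_i <- getp(i, "N"); ca_i <- getp(i, "CA")
    setp(i, "CB", place_atom(cprev, n_i, ca_i, p$b_ca_cb, p$a_n_ca_cb,
                             phi + p$t_cb_offset))
    setp(i, "HA", place_atom(cprev, n_i, ca_i, p$b_c_h, p$a_n_ca_ha,
                             phi + p$t_ha_offset))
    for (k in 1:3) {
      setp(i, paste0("HB", k),
           place_atom(n_i, ca_i, getp(i, "CB"), p$b_c_h, p$a_x_c_h,
                      60 + 120 * (k - 1)))
    }
  }
  ## --- cap methyl hydrogens ---
  for (k in 1:3) {
    setp(0, paste0("HH3", k),
         place_atom(getp(0, "O"), getp(0, "C"), getp(0, "CH3"),
                    p$b_c_h, p$a_x_c_h, 60 + 120 * (k - 1)))
    setp(nres - 1, paste0("HH3", k),
         place_atom(getp(n_ala, "C"), getp(nres - 1, "N"), getp(nres - 1, "CH3"),
                    p$b_c_h, p$a_x_c_h, 60 + 120 * (k - 1)))
  }

  ## --- assemble atom table in canonical order ---
  order_for <- function(res) {
    if (res == 0) c("CH3", "HH31", "HH32", "HH33", "C", "O")
    else if (res == nres - 1) c("N", "H", "CH3", "HH31", "HH32", "HH33")
    else c("N", "H", "CA", "HA", "CB", "HB1", "HB2", "HB3", "C", "O")
  }
  rows <- list()
  for (res in 0:(nres - 1)) {
    rname <- if (res == 0) "ACE" else if (res == nres - 1) "NME" else "ALA"
    for (nm in order_for(res)) {
      xyz <- getp(res, nm)
      rows[[length(rows) + 1]] <- data.frame(
        name = nm, element = element_from_name(nm),
        residue_index = res, residue_name = rname,
        x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("helixhb: construction produced non-finite coordinates", call. = FALSE)
  }
  new_peptide_structure(atoms, n_ala, phi, psi, omega, label)
}

#' Build a helix model with standard dihedral presets
#'
#' Convenience wrapper around [build_capped_polyalanine()] with the
#' 3_10-helix preset `phi = -49, psi = -26` or the alpha-helix preset
#' `phi = -57, psi = -47`, and a conventional label (`WH_3-10-<n>` or
#' `WH_a-<n>`).
#'
#' @param helix `"310"` or `"alpha"`.
#' @inheritParams build_capped_polyalanine
#' @export
build_helix <- function(helix = c("310", "alpha"), n_ala, params = geometry_params()) {
  helix <- match.arg(helix)
  if (helix == "310") {
    build_capped_polyalanine(n_ala, -49, -26, params,
                             label = sprintf("WH_3-10-%d", n_ala))
  } else {
    build_capped_polyalanine(n_ala, -57, -47, params,
                             label = sprintf("WH_a-%d", n_ala))
  }
}

resolve_selector <- function(structure, sel) {
  if (is.numeric(sel) && length(sel) == 1) {
    if (sel < 1 || sel > nrow(structure$atoms)) {
      stop("helixhb: atom index out of range", call. = FALSE)
    }
    return(as.numeric(structure$atoms[sel, c("x", "y", "z")]))
  }
  if (length(sel) == 2) return(atom_xyz(structure, as.integer(sel[[1]]), as.character(sel[[2]])))
  stop("helixhb: atom selector must be an atom row index or (residue_index, name)",
       call. = FALSE)
}

#' Measure a dihedral angle on a structure
#'
#' @param structure A `peptide_structure`.
#' @param selectors A list of four atom selectors, each either an atom row
#'   index or a `list(residue_index, name)` pair.
#' @return Signed dihedral in degrees in `[-180, 180)`.
#' @examples
#' wh <- build_capped_polyalanine(2, -49, -26)
#' measure_dihedral(wh, list(list(0, "C"), list(1, "N"), list(1, "CA"), list(1, "C")))
#' @export
measure_dihedral <- function(structure, selectors) {
  stopifnot(inherits(structure, "peptide_structure"))
  if (length(selectors) != 4) stop("helixhb: need exactly four atom selectors", call. = FALSE)
  pts <- lapply(selectors, resolve_selector, structure = structure)
  if (anyDuplicated(do.call(rbind, pts))) {
    stop("helixhb: the four atoms must be distinct", call. = FALSE)
  }
  dihedral_points(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
}

#' Re-measure backbone dihedrals of every alanine
#'
#' @param structure A `peptide_structure` with Ace/Nme caps.
#' @return Data frame with one row per alanine: `residue_index`, `phi`,
#'   `psi`, `omega` (omega of the peptide bond preceding the residue).
#' @export
measure_phi_psi <- function(structure) {
  n <- structure$n_ala
  res <- lapply(seq_len(n), function(i) {
    ca_prev <- if (i == 1) list(0, "CH3") else list(i - 1, "CA")
    data.frame(
      residue_index = i,
      phi = measure_dihedral(structure, list(list(i - 1, "C"), list(i, "N"),
                                             list(i, "CA"), list(i, "C"))),
      psi = measure_dihedral(structure, list(list(i, "N"), list(i, "CA"),
                                             list(i, "C"), list(i + 1, "N"))),
      omega = measure_dihedral(structure, list(ca_prev, list(i - 1, "C"),
                                               list(i, "N"), list(i, "CA")))
    )
  })
  do.call(rbind, res)
}

#' Write a structure to a PDB file
#'
#' Single-MODEL ATOM records with standard ACE/ALA/NME residue names,
#' written through \pkg{bio3d}.
#'
#' @param structure A `peptide_structure`.
#' @param path Output file path.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "peptide_structure"))
  a <- structure$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$residue_index + 1,
                   resid = a$residue_name,
                   elety = a$name,
                   eleno = seq_len(nrow(a)),
                   chain = rep("A", nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' Read a PDB file into a peptide structure
#'
#' Parses ATOM/HETATM records via \pkg{bio3d}. Residue numbering is
#' renormalized so the first residue has index 0 (the Ace cap slot).
#' Malformed coordinate fields are reported with their line number.
#'
#' @param path PDB file path.
#' @return A `peptide_structure`. `phi`/`psi`/`omega` construction targets
#'   are `NA` (measure them with [measure_phi_psi()] if the backbone is
#'   complete).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("helixhb: file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop(sprintf("helixhb: malformed PDB record at line %d: record too short", i),
           call. = FALSE)
    }
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (any(is.na(coords))) {
      stop(sprintf("helixhb: malformed PDB record at line %d: unparseable coordinates", i),
           call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  res0 <- a$resno - min(a$resno)
  atoms <- data.frame(
    name = a$elety, element = element_from_name(a$elety),
    residue_index = res0, residue_name = a$resid,
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  n_ala <- sum(tapply(atoms$residue_name, atoms$residue_index, function(r) r[1] == "ALA"))
  new_peptide_structure(atoms, as.integer(n_ala),
                        label = sub("\\.pdb$", "", basename(path)))
}

#' Apply a rigid-body transform to a structure
#'
#' Rotates coordinates by `rotation` (3x3 matrix) and then translates by
#' `translation`. Used to verify that internal coordinates, hydrogen-bond
#' geometry, and local dipole norms are frame independent.
#'
#' @param structure A `peptide_structure`.
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation Numeric 3-vector (default zero).
#' @export
transform_structure <- function(structure, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(structure, "peptide_structure"))
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}
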