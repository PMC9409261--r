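MODEL_KINDS <- c("WH", "ST", "MH", "ST_EC", "ST_EN", "ST_ECN", "ST_E2N")

# Turn residue `res` of `atoms` into an Ace cap: keep C/O, the alpha carbon
# becomes the methyl carbon (renamed CH3), HA becomes a methyl H, and the
# severed N- and CB-bonds are capped with H along the former bond vectors.
residue_to_ace <- function(atoms, res, ch_len) {
  sel <- atoms$residue_index == res
  if (atoms$residue_name[sel][1] == "ACE") {
    out <- atoms[sel, , drop = FALSE]
    out$residue_name <- "ACE"
    return(out)
  }
  get <- function(nm) as.numeric(atoms[sel & atoms$name == nm, c("x", "y", "z")])
  ca <- get("CA")
  caps <- lapply(c("N", "CB"), function(nm) {
    tgt <- get(nm)
    ca + ch_len * (tgt - ca) / vnorm(tgt - ca)
  })
  mk <- function(nm, el, xyz) data.frame(name = nm, element = el,
                                         residue_index = res, residue_name = "ACE",
                                         x = xyz[1], y = xyz[2], z = xyz[3],
                                         stringsAsFactors = FALSE)
  rbind(mk("CH3", "C", ca),
        mk("HH31", "H", get("HA")),
        mk("HH32", "H", caps[[1]]),
        mk("HH33", "H", caps[[2]]),
        mk("C", "C", get("C")),
        mk("O", "O", get("O")))
}

# Turn residue `res` into an Nme cap: keep N/H, CA becomes the methyl carbon.
residue_to_nme <- function(atoms, res, ch_len) {
  sel <- atoms$residue_index == res
  if (atoms$residue_name[sel][1] == "NME") {
    out <- atoms[sel, , drop = FALSE]
    return(out)
  }
  get <- function(nm) as.numeric(atoms[sel & atoms$name == nm, c("x", "y", "z")])
  ca <- get("CA")
  caps <- lapply(c("C", "CB"), function(nm) {
    tgt <- get(nm)
    ca + ch_len * (tgt - ca) / vnorm(tgt - ca)
  })
  mk <- function(nm, el, xyz) data.frame(name = nm, element = el,
                                         residue_index = res, residue_name = "NME",
                                         x = xyz[1], y = xyz[2], z = xyz[3],
                                         stringsAsFactors = FALSE)
  rbind(mk("N", "N", get("N")),
        mk("H", "H", get("H")),
        mk("CH3", "C", ca),
        mk("HH31", "H", get("HA")),
        mk("HH32", "H", caps[[1]]),
        mk("HH33", "H", caps[[2]]))
}

renumber_residues <- function(atoms) {
  old <- sort(unique(atoms$residue_index))
  atoms$residue_index <- match(atoms$residue_index, old) - 1L
  rownames(atoms) <- NULL
  atoms
}

extract_window <- function(wh, left, right, label) {
  atoms <- wh$atoms
  parts <- list(residue_to_ace(atoms, left, geometry_params()$b_c_h))
  if (right - left >= 2) {
    for (r in (left + 1):(right - 1)) {
      parts[[length(parts) + 1]] <- atoms[atoms$residue_index == r, , drop = FALSE]
    }
  }
  parts[[length(parts) + 1]] <- residue_to_nme(atoms, right, geometry_params()$b_c_h)
  out <- renumber_residues(do.call(rbind, parts))
  new_peptide_structure(out, n_ala = as.integer(right - left - 1),
                        phi = wh$phi, psi = wh$psi, omega = wh$omega, label = label)
}

#' Derive a simplified model structure for one hydrogen-bond pair
#'
#' Carves the single-turn (ST), minimal hydrogen-bond (MH), or extended
#' single-turn (ST_EC / ST_EN / ST_ECN / ST_E2N) model for a pair out of
#' its parent whole-helix (WH) model. All atoms shared with the parent keep
#' bit-identical coordinates; only the new capping groups introduce atoms
#' (methyl hydrogens placed along former bond vectors).
#'
#' * `ST`: the residues from the acceptor to the donor, with the acceptor
#'   residue collapsed to an Ace cap (keeping its C=O) and the donor
#'   residue to an Nme cap (keeping its N-H): Ace-(Ala)2-Nme for offset 3.
#' * `ST_EC` / `ST_EN` / `ST_ECN` / `ST_E2N`: the ST window extended by one
#'   residue C-terminally, one N-terminally, both, or two N-terminally.
#' * `MH`: two separated N-methylacetamide molecules carrying the acceptor
#'   and donor peptide groups (12 atoms each); residue indices 0-1 and 2-3.
#'
#' @param wh The parent `peptide_structure`.
#' @param pair One row from [detect_hbond_pairs()] on `wh`.
#' @param kind One of `"WH"`, `"ST"`, `"MH"`, `"ST_EC"`, `"ST_EN"`,
#'   `"ST_ECN"`, `"ST_E2N"`.
#' @return A `peptide_structure` with attribute `target_pair`, a one-row
#'   data frame locating the pair in the new residue numbering.
#' @export
extract_model <- function(wh, pair, kind = "ST") {
  stopifnot(inherits(wh, "peptide_structure"))
  kind <- match.arg(kind, MODEL_KINDS)
  pair <- pair_row(pair)
  a <- pair$acceptor_res
  d <- pair$donor_res
  last_res <- max(wh$atoms$residue_index)

  if (kind == "WH") {
    out <- wh
    attr(out, "target_pair") <- pair
    return(out)
  }
  if (kind == "MH") {
    p <- geometry_params()$b_c_h
    atoms <- wh$atoms
    mol_a <- rbind(residue_to_ace(atoms, a, p), residue_to_nme(atoms, a + 1, p))
    mol_d <- rbind(residue_to_ace(atoms, d - 1, p), residue_to_nme(atoms, d, p))
    mol_a$residue_index <- rep(c(0L, 1L), times = c(6L, 6L))
    mol_d$residue_index <- rep(c(2L, 3L), times = c(6L, 6L))
    out <- new_peptide_structure(rbind(mol_a, mol_d), n_ala = 0L,
                                 phi = wh$phi, psi = wh$psi, omega = wh$omega,
                                 label = sprintf("MH_%s", pair$label))
    tp <- pair
    tp$acceptor_res <- 0L
    tp$donor_res <- 3L
    attr(out, "target_pair") <- tp
    return(out)
  }
  win <- switch(kind,
                ST = c(a, d),
                ST_EC = c(a, d + 1),
                ST_EN = c(a - 1, d),
                ST_ECN = c(a - 1, d + 1),
                ST_E2N = c(a - 2, d))
  if (win[1] < 0 || win[2] > last_res) {
    stop(sprintf("helixhb: model %s is not derivable for pair %s (window %d..%d outside residues 0..%d)",
                 kind, pair$label, win[1], win[2], last_res), call. = FALSE)
  }
  out <- extract_window(wh, win[1], win[2], sprintf("%s_%s", kind, pair$label))
  tp <- pair
  tp$acceptor_res <- a - win[1]
  tp$donor_res <- d - win[1]
  attr(out, "target_pair") <- tp
  out
}

add_cap_h <- function(atoms, res, base_name, removed_xyz, len) {
  sel <- atoms$residue_index == res & atoms$name == base_name
  if (sum(sel) != 1) {
    stop(sprintf("helixhb: missing atom %s in residue %d while capping", base_name, res),
         call. = FALSE)
  }
  base <- as.numeric(atoms[sel, c("x", "y", "z")])
  xyz <- base + len * (removed_xyz - base) / vnorm(removed_xyz - base)
  k <- sum(atoms$residue_index == res & startsWith(atoms$name, "HX")) + 1
  rbind(atoms, data.frame(name = paste0("HX", k), element = "H",
                          residue_index = res,
                          residue_name = atoms$residue_name[sel][1],
                          x = xyz[1], y = xyz[2], z = xyz[3],
                          stringsAsFactors = FALSE))
}

delete_group <- function(structure, pair, what = c("acceptor", "donor")) {
  what <- match.arg(what)
  atoms <- structure$atoms
  p <- geometry_params()
  if (what == "acceptor") {
    res <- pair$acceptor_res
    doomed <- atoms$residue_index == res & atoms$name %in% c("C", "O")
    if (sum(doomed) != 2) {
      stop(sprintf("helixhb: residue %d lacks its carbonyl C/O atoms", res), call. = FALSE)
    }
    c_xyz <- as.numeric(atoms[atoms$residue_index == res & atoms$name == "C",
                              c("x", "y", "z")])
    kept <- atoms[!doomed, , drop = FALSE]
    prev_c <- if (any(kept$residue_index == res & kept$name == "CA")) "CA" else "CH3"
    kept <- add_cap_h(kept, res, prev_c, c_xyz, p$b_c_h)
    kept <- add_cap_h(kept, res + 1, "N", c_xyz, p$b_n_h)
  } else {
    res <- pair$donor_res
    doomed <- atoms$residue_index == res & atoms$name %in% c("N", "H")
    if (sum(doomed) != 2) {
      stop(sprintf("helixhb: residue %d lacks its amide N/H atoms", res), call. = FALSE)
    }
    n_xyz <- as.numeric(atoms[atoms$residue_index == res & atoms$name == "N",
                              c("x", "y", "z")])
    kept <- atoms[!doomed, , drop = FALSE]
    kept <- add_cap_h(kept, res - 1, "C", n_xyz, p$b_c_h)
    next_c <- if (any(kept$residue_index == res & kept$name == "CA")) "CA" else "CH3"
    kept <- add_cap_h(kept, res, next_c, n_xyz, p$b_c_h)
  }
  out <- structure
  out$atoms <- kept
  rownames(out$atoms) <- NULL
  out$label <- paste0(structure$label, if (what == "acceptor") "-minusA" else "-minusD")
  out
}

#' Build the four NFA fragment systems for a hydrogen-bond pair
#'
#' Produces the entire system plus the three deletion fragments used by the
#' negative fragmentation approach: the system lacking the acceptor group
#' (the acceptor residue's carbonyl C and O removed), the system lacking
#' the donor group (the donor residue's amide N and H removed), and the
#' system lacking both. Each severed bond is capped with a hydrogen placed
#' along the former bond vector (C-H 1.090 A on carbon, N-H 1.010 A on
#' nitrogen), so every fragment keeps the same atom count as the parent.
#' The two deletions commute atom-for-atom.
#'
#' @param model A `peptide_structure` (typically from [extract_model()]).
#' @param pair One-row pair data frame in `model`'s numbering; defaults to
#'   the model's `target_pair` attribute.
#' @return A list of class `fragment_set` with elements `sys`, `minus_A`,
#'   `minus_D`, `minus_AD`.
#' @export
make_nfa_fragments <- function(model, pair = attr(model, "target_pair")) {
  stopifnot(inherits(model, "peptide_structure"))
  if (is.null(pair)) stop("helixhb: no pair given and model carries no target_pair",
                          call. = FALSE)
  pair <- pair_row(pair)
  minus_a <- delete_group(model, pair, "acceptor")
  minus_d <- delete_group(model, pair, "donor")
  minus_ad <- delete_group(minus_a, pair, "donor")
  minus_ad$label <- paste0(model$label, "-minusAD")
  structure(list(sys = model, minus_A = minus_a, minus_D = minus_d,
                 minus_AD = minus_ad, pair = pair),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> pair %s: sys %d atoms, fragments %d/%d/%d atoms\n",
              x$pair$label, nrow(x$sys$atoms), nrow(x$minus_A$atoms),
              nrow(x$minus_D$atoms), nrow(x$minus_AD$atoms)))
  invisible(x)
}
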