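#' Enumerate backbone hydrogen-bond pairs by residue offset
#'
#' Pairing is purely topological: the C=O of residue `i` is paired with the
#' N-H of residue `i + offset`, for every `i` where both groups exist. No
#' distance or angle cutoff is applied (helical H-bonds are defined by the
#' backbone topology, offset 3 for a 3_10-helix and 4 for an alpha-helix).
#' The Ace cap (residue 0) contributes a C=O acceptor and the Nme cap
#' (residue `n_ala + 1`) an N-H donor, so an Ace-(Ala)n-Nme model has
#' `n - 1` pairs at offset 3 and `n - 2` at offset 4 (floored at 0).
#'
#' @param structure A `peptide_structure` with caps.
#' @param offset Donor minus acceptor residue index, 3 or 4.
#' @return Data frame with columns `label` (the "n-s" name, s counted from
#'   the N-terminus), `s`, `acceptor_res`, `donor_res`, `offset`, and the
#'   positional-class columns `class` / `adjacent_to_terminal` (filled by
#'   [classify_pair_position()], `NA`/`FALSE` here). Zero rows if the chain
#'   is shorter than the offset.
#' @examples
#' wh <- build_helix("310", 7)
#' detect_hbond_pairs(wh, 3)$label  # "7-1" .. "7-6"
#' @export
detect_hbond_pairs <- function(structure, offset = 3) {
  stopifnot(inherits(structure, "peptide_structure"))
  if (!offset %in% c(3, 4)) stop("helixhb: offset must be 3 or 4", call. = FALSE)
  last_res <- max(structure$atoms$residue_index)
  acceptors <- if (last_res >= offset) 0:(last_res - offset) else integer(0)
  n_pairs <- length(acceptors)
  if (n_pairs == 0) {
    return(data.frame(label = character(0), s = integer(0),
                      acceptor_res = integer(0), donor_res = integer(0),
                      offset = integer(0), class = character(0),
                      adjacent_to_terminal = logical(0),
                      stringsAsFactors = FALSE))
  }
  for (a in acceptors) {
    d <- a + offset
    for (nm in c("C", "O")) {
      if (!has_atom(structure, a, nm)) {
        stop(sprintf("helixhb: residue %d is missing its %s atom (C=O acceptor group)",
                     a, nm), call. = FALSE)
      }
    }
    for (nm in c("N", "H")) {
      if (!has_atom(structure, d, nm)) {
        stop(sprintf("helixhb: residue %d is missing its %s atom (N-H donor group)",
                     d, nm), call. = FALSE)
      }
    }
  }
  data.frame(
    label = sprintf("%d-%d", structure$n_ala, seq_len(n_pairs)),
    s = seq_len(n_pairs),
    acceptor_res = as.integer(acceptors),
    donor_res = as.integer(acceptors + offset),
    offset = as.integer(offset),
    class = NA_character_,
    adjacent_to_terminal = FALSE,
    stringsAsFactors = FALSE
  )
}

pair_row <- function(pair) {
  if (is.data.frame(pair)) {
    if (nrow(pair) != 1) stop("helixhb: expected a single pair row", call. = FALSE)
    return(pair)
  }
  stop("helixhb: pair must be a one-row data frame from detect_hbond_pairs()",
       call. = FALSE)
}

#' Hydrogen-bond O...H distance
#'
#' Euclidean distance between the acceptor carbonyl oxygen and the donor
#' amide hydrogen of one pair.
#'
#' @param structure A `peptide_structure`.
#' @param pair One row of the data frame from [detect_hbond_pairs()].
#' @return Distance in Angstrom.
#' @export
hbond_distance <- function(structure, pair) {
  pair <- pair_row(pair)
  o <- atom_xyz(structure, pair$acceptor_res, "O")
  h <- atom_xyz(structure, pair$donor_res, "H")
  d <- vnorm(o - h)
  if (d < 1e-8) stop("helixhb: degenerate geometry, acceptor O and donor H coincide",
                     call. = FALSE)
  d
}

#' Hydrogen-bond C-O...N-H torsion angle
#'
#' Signed dihedral over the atoms C, O (acceptor carbonyl) and N, H (donor
#' amide), in that order: the angle between the C=O and N-H bond vectors
#' about the O...N axis.
#'
#' @inheritParams hbond_distance
#' @return Degrees in `[-180, 180)`.
#' @export
hbond_torsion <- function(structure, pair) {
  pair <- pair_row(pair)
  dihedral_points(atom_xyz(structure, pair$acceptor_res, "C"),
                  atom_xyz(structure, pair$acceptor_res, "O"),
                  atom_xyz(structure, pair$donor_res, "N"),
                  atom_xyz(structure, pair$donor_res, "H"))
}

#' Assign positional classes to hydrogen-bond pairs
#'
#' The first and last pairs (counting from the N-terminus) are `terminal`;
#' the pairs immediately inside them are `adjacent`; the rest are `inner`.
#' When only two pairs exist the N-terminal pair is adjacent to the
#' C-terminal pair and vice versa, so both are classed `terminal` *and*
#' flagged `adjacent_to_terminal`, contributing to both groups in
#' positional statistics. A single pair is terminal only.
#'
#' @param pairs Data frame from [detect_hbond_pairs()] (non-empty, one
#'   structure).
#' @return The same data frame with `class` and `adjacent_to_terminal`
#'   filled in.
#' @export
classify_pair_position <- function(pairs) {
  if (!is.data.frame(pairs) || nrow(pairs) == 0) {
    stop("helixhb: pair list must be a non-empty data frame", call. = FALSE)
  }
  n <- nrow(pairs)
  cls <- rep("inner", n)
  if (n >= 2) cls[c(2, n - 1)] <- "adjacent"
  cls[c(1, n)] <- "terminal"
  pairs$class <- cls
  pairs$adjacent_to_terminal <- seq_len(n) %in% c(2, n - 1)
  pairs
}

pop_sd <- function(x) {
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Summarize hydrogen-bond geometry over a set of structures
#'
#' Computes per-pair O...H distances and C-O...N-H torsions for every
#' structure, classifies pair positions, and tabulates mean +/- standard
#' deviation of the distances by positional class and overall. The terminal
#' and adjacent groups follow the two-pair double-counting rule of
#' [classify_pair_position()]. Standard deviations are population standard
#' deviations (n in the denominator).
#'
#' @param structures A list of `peptide_structure` objects.
#' @param offset Residue offset passed to [detect_hbond_pairs()].
#' @return A list of class `geometry_summary` with `per_pair` (model,
#'   label, class, adjacent_to_terminal, distance_A, torsion_deg) and
#'   `by_class` (group, n, mean_A, sd_A; groups terminal / adjacent /
#'   inner / all).
#' @export
summarize_geometry <- function(structures, offset = 3) {
  if (!is.list(structures) || length(structures) == 0) {
    stop("helixhb: need at least one structure", call. = FALSE)
  }
  per <- lapply(structures, function(s) {
    pr <- classify_pair_position(detect_hbond_pairs(s, offset))
    pr$model <- s$label
    pr$distance_A <- vapply(seq_len(nrow(pr)), function(i) hbond_distance(s, pr[i, ]),
                            numeric(1))
    pr$torsion_deg <- vapply(seq_len(nrow(pr)), function(i) hbond_torsion(s, pr[i, ]),
                             numeric(1))
    pr
  })
  per <- do.call(rbind, per)
  groups <- list(
    terminal = per$class == "terminal",
    adjacent = per$class == "adjacent" | per$adjacent_to_terminal,
    inner = per$class == "inner",
    all = rep(TRUE, nrow(per))
  )
  by_class <- do.call(rbind, lapply(names(groups), function(g) {
    d <- per$distance_A[groups[[g]]]
    data.frame(group = g, n = length(d), mean_A = mean(d), sd_A = pop_sd(d),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_pair = per, by_class = by_class, offset = offset),
            class = "geometry_summary")
}

#' @export
print.geometry_summary <- function(x, ...) {
  cat(sprintf("<geometry_summary> offset %d, %d pairs from %d models\n",
              x$offset, nrow(x$per_pair), length(unique(x$per_pair$model))))
  print(transform(x$by_class, mean_A = round(mean_A, 3), sd_A = round(sd_A, 3)))
  invisible(x)
}
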