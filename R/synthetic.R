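# Unit in the last place of x; used to put synthetic baselines on a grid
# commensurate with a designed value so that the four-term NFA combination
# cancels in floating point without rounding.
ulp_of <- function(x) {
  if (x == 0) return(2^-52)
  2^(floor(log2(abs(x))) - 52)
}

#' Generate synthetic fragment-energy quadruples with a designed H-bond energy
#'
#' Constructs `e_sys = e_minus_A + e_minus_D - e_minus_AD + designed_ehb`
#' with randomized baselines, so that [nfa_combine()] recovers the designed
#' energy. The baselines are drawn on a binary grid commensurate with the
#' designed value (and bounded so that every partial sum stays within one
#' binade of exactness), which makes the recovery bit-exact rather than
#' merely accurate to rounding; `baseline_scale` is therefore capped at 0.5
#' kcal/mol. This is an algebraic oracle for the combination formula, not
#' an emulation of quantum-chemical total energies (which are many orders
#' of magnitude larger; the combination is shift-invariant, so the baseline
#' magnitude carries no information).
#'
#' @param designed_ehb Numeric vector of designed hydrogen-bond energies
#'   (kcal/mol), one per synthetic pair.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param baseline_scale Half-width of the uniform baseline draw (kcal/mol,
#'   capped at 0.5).
#' @return Data frame with `pair`, `e_sys`, `e_minus_A`, `e_minus_D`,
#'   `e_minus_AD`, `designed` columns.
#' @export
gen_fragment_energies <- function(designed_ehb, seed = 1, baseline_scale = 0.5) {
  if (any(!is.finite(designed_ehb))) {
    stop("helixhb: designed energies must be finite", call. = FALSE)
  }
  scale <- min(abs(baseline_scale), 0.5)
  rows <- withr::with_seed(seed, {
    lapply(seq_along(designed_ehb), function(i) {
      e <- designed_ehb[i]
      g <- ulp_of(e)
      # largest magnitude exactly representable on the grid of e's ulp;
      # keep every partial sum below it so no combination step rounds
      bound <- g * 2^53
      sc <- min(scale, (bound - abs(e)) / 8)
      draw <- function() round(stats::runif(1, -sc, sc) / g) * g
      a <- draw(); d <- draw(); ad <- draw()
      data.frame(pair = i, e_sys = ((a + d) - ad) + e, e_minus_A = a,
                 e_minus_D = d, e_minus_AD = ad, designed = e)
    })
  })
  do.call(rbind, rows)
}

gaussian_blob_values <- function(grid_geom, center, width, amplitude) {
  shape <- grid_geom$shape
  idx <- expand.grid(ix = seq_len(shape[1]) - 1, iy = seq_len(shape[2]) - 1,
                     iz = seq_len(shape[3]) - 1)
  pts <- as.matrix(idx) %*% grid_geom$axes
  pts <- sweep(pts, 2, grid_geom$origin, "+")
  d2 <- rowSums(sweep(pts, 2, center, "-")^2)
  array(amplitude * exp(-d2 / (2 * width^2)), dim = shape)
}

quantize <- function(values, g = 2^-55) round(values / g) * g

#' Generate a synthetic four-cube quadruple with a designed density change
#'
#' Builds fragment densities obeying
#' `rho_sys = rho_minusA + rho_minusD - rho_minusAD + delta` where `delta`
#' is a designed sum of Gaussian blobs (e.g. a positive lobe near the
#' acceptor oxygen and a negative lobe near the donor hydrogen, the
#' signature of H-bond formation). All fields are quantized to multiples
#' of 2^-55 a.u. (about 2.8e-17, far below any density of interest) so the
#' voxelwise combination recovers the returned `delta` bit-exactly.
#'
#' @param blobs Data frame with columns `cx`, `cy`, `cz` (Bohr), `width`
#'   (Bohr, > 0), `amplitude` (a.u.).
#' @param grid_geom List with `origin` (3-vector, Bohr), `axes` (3x3,
#'   Bohr), `shape` (3 integers).
#' @param seed Integer seed for the random baseline fields.
#' @param baseline_amplitude Scale of the smooth random baseline densities
#'   (a.u.).
#' @param atoms Optional atom table carried into the grids.
#' @return List with `sys`, `minus_A`, `minus_D`, `minus_AD`, `delta`
#'   (`density_grid` objects).
#' @export
gen_synthetic_cubes <- function(blobs, grid_geom, seed = 1,
                                baseline_amplitude = 0.02, atoms = NULL) {
  if (any(blobs$width <= 0)) stop("helixhb: blob widths must be positive", call. = FALSE)
  shape <- grid_geom$shape
  # warn (not error) about blob centers outside the grid box
  lo <- grid_geom$origin
  hi <- grid_geom$origin + as.numeric((shape - 1) %*% grid_geom$axes)
  for (i in seq_len(nrow(blobs))) {
    ctr <- as.numeric(blobs[i, c("cx", "cy", "cz")])
    if (any(ctr < pmin(lo, hi)) || any(ctr > pmax(lo, hi))) {
      warning(sprintf("helixhb: blob %d center lies outside the grid box", i),
              call. = FALSE)
    }
  }
  delta <- array(0, dim = shape)
  for (i in seq_len(nrow(blobs))) {
    delta <- delta + gaussian_blob_values(grid_geom,
                                          as.numeric(blobs[i, c("cx", "cy", "cz")]),
                                          blobs$width[i], blobs$amplitude[i])
  }
  delta <- quantize(delta)
  base <- withr::with_seed(seed, {
    lapply(1:3, function(k) quantize(array(abs(stats::rnorm(prod(shape),
                                                            mean = baseline_amplitude,
                                                            sd = baseline_amplitude / 4)),
                                           dim = shape)))
  })
  minus_a <- base[[1]]; minus_d <- base[[2]]; minus_ad <- base[[3]]
  sys <- ((minus_a + minus_d) - minus_ad) + delta
  g <- function(v) density_grid(grid_geom$origin, grid_geom$axes, v, atoms)
  list(sys = g(sys), minus_A = g(minus_a), minus_D = g(minus_d),
       minus_AD = g(minus_ad), delta = g(delta))
}

#' Generate charges reproducing designed local dipole norms
#'
#' Inverts the two-point dipole formula for each requested group: given the
#' structure's bond vector, assigns the two atomic charges symmetrically
#' about a random baseline so that [local_group_dipole()] returns the
#' designed norm (to floating-point rounding, well below 1e-10 D).
#'
#' @param structure A `peptide_structure`.
#' @param groups Data frame with columns `group` ("CO"/"NH"),
#'   `residue_index`, `designed_norm` (Debye, >= 0).
#' @param seed Integer seed for the charge baselines.
#' @return A `charge_set` with provenance `"synthetic"`.
#' @export
gen_charge_sets <- function(structure, groups, seed = 1) {
  rows <- withr::with_seed(seed, {
    lapply(seq_len(nrow(groups)), function(i) {
      grp <- groups$group[i]
      res <- groups$residue_index[i]
      atoms <- if (grp == "CO") c("C", "O") else c("H", "N")
      r1 <- atom_xyz(structure, res, atoms[1])
      r2 <- atom_xyz(structure, res, atoms[2])
      bond <- vnorm(r1 - r2)
      if (bond < 1e-8) {
        stop(sprintf("helixhb: degenerate %s bond in residue %d", grp, res),
             call. = FALSE)
      }
      qdiff <- 2 * groups$designed_norm[i] / (bond * EA_TO_DEBYE)
      q0 <- stats::runif(1, -0.2, 0.2)
      data.frame(residue_index = res, atom = atoms,
                 charge = c(q0 + qdiff / 2, q0 - qdiff / 2),
                 stringsAsFactors = FALSE)
    })
  })
  charge_set(structure, do.call(rbind, rows), provenance = "synthetic")
}
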