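#' Construct a volumetric density grid
#'
#' A scalar field with Gaussian-cube semantics: an origin and three axis
#' step vectors in Bohr, a 3-D array of values in atomic units (e/Bohr^3)
#' indexed `[ix, iy, iz]`, and an optional atom list carried for
#' provenance. File order is the cube standard (x outermost, z fastest).
#'
#' @param origin Numeric 3-vector (Bohr).
#' @param axes 3x3 matrix, row `i` = step vector of axis `i` (Bohr).
#' @param values 3-D numeric array.
#' @param atoms Optional data frame `number`, `charge`, `x`, `y`, `z`
#'   (atomic number and Bohr coordinates).
#' @return Object of class `density_grid`.
#' @export
density_grid <- function(origin, axes, values, atoms = NULL) {
  axes <- as.matrix(axes)
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("helixhb: values must be a 3-D array", call. = FALSE)
  }
  if (length(origin) != 3 || !all(dim(axes) == c(3, 3))) {
    stop("helixhb: origin must be length 3 and axes 3x3", call. = FALSE)
  }
  if (abs(det(axes)) < 1e-12) {
    stop("helixhb: degenerate axes, voxel volume is zero", call. = FALSE)
  }
  if (is.null(atoms)) {
    atoms <- data.frame(number = integer(0), charge = numeric(0),
                        x = numeric(0), y = numeric(0), z = numeric(0))
  }
  structure(list(origin = as.numeric(origin), axes = axes,
                 shape = dim(values), values = values, atoms = atoms),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d x %d voxels, voxel volume %.6g Bohr^3, %d atoms\n",
              x$shape[1], x$shape[2], x$shape[3], abs(det(x$axes)), nrow(x$atoms)))
  cat(sprintf("  values in [%.3e, %.3e], integral %.6g e\n",
              min(x$values), max(x$values), grid_integral(x)))
  invisible(x)
}

#' Read a Gaussian cube file
#'
#' Standard density-dialect layout: two comment lines; atom count and
#' origin; three axis records; atom records; values six per line in
#' z-fastest order. A negative atom count (the molecular-orbital dialect)
#' is rejected as unsupported.
#'
#' @param path Cube file path.
#' @return A `density_grid`.
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("helixhb: file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("helixhb: cube parse error: file too short", call. = FALSE)
  nums <- function(ln) as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  hdr <- nums(lines[3])
  natoms <- hdr[1]
  if (is.na(natoms)) stop("helixhb: cube parse error in header line 3", call. = FALSE)
  if (natoms < 0) {
    stop("helixhb: unsupported cube dialect (negative atom count / orbital cube)",
         call. = FALSE)
  }
  origin <- hdr[2:4]
  shape <- integer(3)
  axes <- matrix(0, 3, 3)
  for (i in 1:3) {
    v <- nums(lines[3 + i])
    shape[i] <- as.integer(v[1])
    axes[i, ] <- v[2:4]
  }
  if (any(shape <= 0)) stop("helixhb: cube parse error: non-positive grid shape",
                            call. = FALSE)
  atoms <- NULL
  if (natoms > 0) {
    at <- do.call(rbind, lapply(lines[6 + seq_len(natoms)], nums))
    atoms <- data.frame(number = as.integer(at[, 1]), charge = at[, 2],
                        x = at[, 3], y = at[, 4], z = at[, 5])
  }
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:(6 + natoms))]), "\\s+")))
  vals <- vals[!is.na(vals)]
  expected <- prod(shape)
  if (length(vals) != expected) {
    stop(sprintf("helixhb: cube parse error: expected %d values, found %d",
                 expected, length(vals)), call. = FALSE)
  }
  # file order: x outer, y middle, z fastest -> array index [ix, iy, iz]
  arr <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  density_grid(origin, axes, arr, atoms)
}

#' Write a Gaussian cube file
#'
#' @param grid A `density_grid`.
#' @param path Output path.
#' @param comment Comment placed on the first header line.
#' @export
write_cube <- function(grid, path, comment = "density grid") {
  stopifnot(inherits(grid, "density_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, "z-fastest value order, atomic units"), con)
  fmt3 <- function(n, v) sprintf("%5d%12.6f%12.6f%12.6f", n, v[1], v[2], v[3])
  writeLines(fmt3(nrow(grid$atoms), grid$origin), con)
  for (i in 1:3) writeLines(fmt3(grid$shape[i], grid$axes[i, ]), con)
  if (nrow(grid$atoms) > 0) {
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f", grid$atoms$number,
                       grid$atoms$charge, grid$atoms$x, grid$atoms$y, grid$atoms$z),
               con)
  }
  # one z-run per (x, y) pair, six values per line, as Gaussian writes it
  nz <- grid$shape[3]
  out <- character(0)
  for (ix in seq_len(grid$shape[1])) {
    for (iy in seq_len(grid$shape[2])) {
      zrun <- grid$values[ix, iy, ]
      starts <- seq(1, nz, by = 6)
      out <- c(out, vapply(starts, function(s) {
        paste(sprintf("%13.5E", zrun[s:min(s + 5, nz)]), collapse = "")
      }, character(1)))
    }
  }
  writeLines(out, con)
  invisible(path)
}

check_compatible <- function(a, b, tol = 1e-8) {
  if (!all(a$shape == b$shape)) {
    stop("helixhb: incompatible grids: shape differs (",
         paste(a$shape, collapse = "x"), " vs ", paste(b$shape, collapse = "x"), ")",
         call. = FALSE)
  }
  if (max(abs(a$origin - b$origin)) > tol) {
    stop("helixhb: incompatible grids: origin differs beyond tolerance", call. = FALSE)
  }
  if (max(abs(a$axes - b$axes)) > tol) {
    stop("helixhb: incompatible grids: axes differ beyond tolerance", call. = FALSE)
  }
  invisible(TRUE)
}

#' Density change upon hydrogen-bond formation from four fragment densities
#'
#' Voxelwise `rho_sys - rho_minusA - rho_minusD + rho_minusAD`, the density
#' analogue of the NFA energy combination: the redistribution of electron
#' density attributable to the acceptor-donor interaction.
#'
#' @param sys,minus_A,minus_D,minus_AD Compatible `density_grid` objects
#'   (same shape; origin and axes equal within 1e-8 Bohr).
#' @return A `density_grid` holding the density change.
#' @export
combine_nfa_density <- function(sys, minus_A, minus_D, minus_AD) {
  for (g in list(minus_A, minus_D, minus_AD)) check_compatible(sys, g)
  out <- sys
  out$values <- ((sys$values - minus_A$values) - minus_D$values) + minus_AD$values
  out
}

#' Voxelwise difference of two density grids
#'
#' Used for second differences between the density changes of two model
#' systems (e.g. single-turn minus minimal-H-bond), which expose the
#' depolarization of the donor and acceptor groups by their surroundings.
#'
#' @param a,b Compatible `density_grid` objects.
#' @return A `density_grid` holding `a - b`.
#' @export
density_difference <- function(a, b) {
  check_compatible(a, b)
  out <- a
  out$values <- a$values - b$values
  out
}

#' Integrate a density grid
#'
#' Riemann sum: sum of voxel values times the voxel volume (absolute
#' determinant of the axis matrix). For an electron density this is the
#' electron count.
#'
#' @param grid A `density_grid`.
#' @return Scalar (electrons).
#' @export
grid_integral <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  sum(grid$values) * abs(det(grid$axes))
}

#' Voxel statistics at an isosurface level
#'
#' Counts voxels with value `>= +iso` and `<= -iso` and their summed
#' volume; the voxel counts are non-increasing in `iso`.
#'
#' @param grid A `density_grid`.
#' @param iso Positive isosurface level (atomic units).
#' @return List with `positive` and `negative`, each `(count, volume)`
#'   (volume in Bohr^3).
#' @export
isosurface_voxel_stats <- function(grid, iso) {
  stopifnot(inherits(grid, "density_grid"))
  if (!is.numeric(iso) || length(iso) != 1 || iso <= 0) {
    stop("helixhb: iso level must be a single positive number", call. = FALSE)
  }
  vol <- abs(det(grid$axes))
  npos <- sum(grid$values >= iso)
  nneg <- sum(grid$values <= -iso)
  list(positive = list(count = npos, volume = npos * vol),
       negative = list(count = nneg, volume = nneg * vol))
}
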