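# Shared fixtures, built in code at test time.

# Cached helix models (construction is cheap but used by many tests).
.fixture_env <- new.env(parent = emptyenv())

fixture_helix <- function(helix, n_ala) {
  key <- paste0(helix, "_", n_ala)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- build_helix(helix, n_ala)
  }
  .fixture_env[[key]]
}

fixture_helix_set <- function(helix) {
  ns <- if (helix == "310") 2:7 else 3:8
  lapply(ns, function(n) fixture_helix(helix, n))
}

# A bare structure with explicitly placed atoms, for hand-arithmetic cases.
bare_structure <- function(df, n_ala = 0L) {
  df$element <- helixhb:::element_from_name(df$name)
  helixhb:::new_peptide_structure(
    df[, c("name", "element", "residue_index", "residue_name", "x", "y", "z")],
    n_ala = n_ala, label = "fixture")
}

# Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    q <- qr.Q(qr_)
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

# Independent dihedral oracle: projection ("praxeolitic") formulation,
# distinct from the cross-product/atan2 path used by the package.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(c(b1[2] * v[3] - b1[3] * v[2],
             b1[3] * v[1] - b1[1] * v[3],
             b1[1] * v[2] - b1[2] * v[1]) * w)
  atan2(y, x) * 180 / pi
}

ref_dipole_norms <- function() {
  path <- system.file("extdata", "reference_dipole_norms.csv", package = "helixhb")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

norms_matrix <- function(tab, tbl, quantity) {
  sub <- tab[tab$table == tbl & tab$quantity == quantity, ]
  m <- matrix(sub$norm_debye, nrow = 3, byrow = TRUE,
              dimnames = list(unique(sub$model), unique(sub$pair)))
  m
}
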