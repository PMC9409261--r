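DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n == 0) stop("helixhb: cannot normalize a zero vector", call. = FALSE)
  a / n
}

#' Signed dihedral angle of four points
#'
#' Computes the torsion angle defined by points `p1-p2-p3-p4` using the
#' standard atan2 formulation, with the IUPAC sign convention (clockwise
#' rotation of the far bond viewed along `p2 -> p3` is positive).
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Cartesian coordinates).
#' @return Angle in degrees in `[-180, 180)`; an exact trans arrangement is
#'   reported as `-180`.
#' @export
dihedral_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("helixhb: degenerate geometry, three of the four atoms are collinear",
         call. = FALSE)
  }
  b2u <- b2 / vnorm(b2)
  m1 <- vcross(n1, b2u)
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * RAD2DEG
  if (ang >= 180) ang <- ang - 360
  ang
}

angle_points <- function(p1, p2, p3) {
  v1 <- vunit(p1 - p2)
  v2 <- vunit(p3 - p2)
  acos(max(-1, min(1, sum(v1 * v2)))) * RAD2DEG
}

# NeRF chain extension: place atom D bonded to C so that |C-D| = bond,
# angle(B, C, D) = ang (deg) and torsion(A, B, C, D) = tor (deg).
place_atom <- function(a, b, c, bond, ang, tor) {
  if (bond <= 0) stop("helixhb: bond length must be positive", call. = FALSE)
  bc <- vunit(c - b)
  n <- vcross(b - a, bc)
  if (vnorm(n) < 1e-10) {
    stop("helixhb: degenerate reference frame (collinear A, B, C)", call. = FALSE)
  }
  n <- vunit(n)
  m <- vcross(n, bc)
  ang_r <- ang * DEG2RAD
  tor_r <- tor * DEG2RAD
  d2 <- bond * c(-cos(ang_r), sin(ang_r) * cos(tor_r), sin(ang_r) * sin(tor_r))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
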