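# Low-level 3D geometry kernel.  All user-facing angles are in degrees;
# radians appear only inside the trigonometric calls.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-10) stop("degenerate geometry: zero-length vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Angle at the middle point of three positions
#'
#' @param p1,p2,p3 Numeric 3-vectors (Angstrom).  The angle is measured at
#'   `p2`.
#' @return Angle in degrees, in \[0, 180\].
#' @keywords internal
bond_angle <- function(p1, p2, p3) {
  u <- vunit(p1 - p2)
  v <- vunit(p3 - p2)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Signed torsion angle of four points
#'
#' Computes the dihedral angle p1-p2-p3-p4 with the IUPAC sign convention:
#' 0 for the cis (eclipsed) arrangement, 180 for trans, positive for a
#' clockwise rotation of p4 relative to p1 when viewed from p2 towards p3.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @examples
#' dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))  # cis: 0
#' dihedral(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)) # trans: 180
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("degenerate geometry: collinear points in dihedral", call. = FALSE)
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * vunit(b2))
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF-style) placement: returns the position `d` such
#' that |c-d| = `bond`, the angle b-c-d equals `angle` and the torsion
#' a-b-c-d equals `torsion`.
#'
#' @param a,b,c Reference positions (numeric 3-vectors, Angstrom).
#' @param bond Bond length c-d in Angstrom.
#' @param angle Bond angle b-c-d in degrees.
#' @param torsion Torsion a-b-c-d in degrees (IUPAC convention).
#' @return Numeric 3-vector.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  chi <- deg2rad(torsion)
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(chi), sin(th) * sin(chi))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Rotation matrix for angle deg about unit axis (Rodrigues), used in tests
# and in rigid-motion utilities.
rotation_matrix <- function(axis, deg) {
  u <- vunit(axis)
  th <- deg2rad(deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * (u %o% u)
}
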