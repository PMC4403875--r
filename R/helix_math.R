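# Closed-form mapping from backbone torsions to helical parameters,
# parameter surfaces, a geometric screw-axis fit used as an independent
# oracle, and the classical dipole-dipole interaction formula.

#' Helical parameters from backbone torsions
#'
#' Closed-form winding relations for a regular polypeptide helix built
#' from planar trans amides.  With the sum/difference angles
#' s = (phi + psi)/2 and t = (phi - psi)/2 (radians inside the
#' trigonometric kernel), the per-residue rotation theta satisfies
#'
#'   cos(theta/2) = -0.817 sin(s) + 0.045 sin(t)
#'
#' and the rise per residue d follows from
#'
#'   d sin(theta/2) = -0.68 cos(t) + 2.9 cos(s).
#'
#' Residues per turn is n = 360/theta and pitch (rise per turn) is
#' p = n * d.  The numeric coefficients embed one fixed covalent
#' geometry (the classical model bond lengths and angles), which is why
#' the independent screw-axis oracle agrees most closely with peptides
#' built at the [geometry_set()] `"pauling"` values.
#'
#' @param phi,psi Backbone torsions in degrees.
#' @return List of class `helical_params`: `theta` (degrees per
#'   residue), `n` (residues per turn), `d` (rise per residue,
#'   Angstrom), `p` (pitch, Angstrom per turn).
#' @examples
#' helical_params(-57, -47)  # classical alpha helix: n ~ 3.6
#' helical_params(-49, -26)  # 3_10 helix: n ~ 3
#' @export
helical_params <- function(phi, psi) {
  stopifnot(length(phi) == 1L, length(psi) == 1L,
            is.finite(phi), is.finite(psi))
  s <- deg2rad((phi + psi) / 2)
  t <- deg2rad((phi - psi) / 2)
  ct <- -0.817 * sin(s) + 0.045 * sin(t)
  if (abs(ct) > 1)
    stop(sprintf("no helical solution at (phi=%g, psi=%g): |cos(theta/2)| = %.3f > 1",
                 phi, psi, abs(ct)), call. = FALSE)
  half <- acos(ct)
  if (sin(half) < 1e-12)
    stop("degenerate helix: theta = 0 (infinite residues per turn)",
         call. = FALSE)
  theta <- rad2deg(2 * half)
  d <- (-0.68 * cos(t) + 2.9 * cos(s)) / sin(half)
  n <- 360 / theta
  structure(list(theta = theta, n = n, d = d, p = n * d),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("theta = %.3f deg/residue  n = %.3f res/turn  d = %.3f A  p = %.3f A/turn\n",
              x$theta, x$n, x$d, x$p))
  invisible(x)
}

#' Helical-parameter surface over a (phi, psi) grid
#'
#' Evaluates the closed-form winding relations on a dense grid.  Cells
#' where |cos(theta/2)| > 1 (no real helical solution) are flagged
#' invalid with `NA` parameters rather than raising an error.
#'
#' @param phi_range,psi_range Length-2 numeric ranges in degrees.
#' @param step Grid step in degrees (> 0).
#' @return Data frame with columns phi, psi, theta, n, d, p, valid.
#' @export
parameter_surface <- function(phi_range = c(-180, 180),
                              psi_range = c(-180, 180), step = 1) {
  stopifnot(step > 0)
  phis <- seq(min(phi_range), max(phi_range), by = step)
  psis <- seq(min(psi_range), max(psi_range), by = step)
  g <- expand.grid(phi = phis, psi = psis, KEEP.OUT.ATTRS = FALSE)
  s <- deg2rad((g$phi + g$psi) / 2)
  t <- deg2rad((g$phi - g$psi) / 2)
  ct <- -0.817 * sin(s) + 0.045 * sin(t)
  half <- acos(pmin(1, pmax(-1, ct)))
  valid <- abs(ct) <= 1 & sin(half) > 1e-12
  theta <- ifelse(valid, rad2deg(2 * half), NA_real_)
  d <- ifelse(valid, (-0.68 * cos(t) + 2.9 * cos(s)) / sin(half), NA_real_)
  n <- 360 / theta
  data.frame(phi = g$phi, psi = g$psi, theta = theta, n = n, d = d,
             p = n * d, valid = valid)
}

#' Fit a screw axis to consecutive C-alpha positions
#'
#' Independent geometric oracle for helical parameters: superposes the
#' window of C-alpha atoms i..i+window onto the window shifted by one
#' residue (Kabsch rigid superposition via SVD), extracts the rotation
#' angle of the optimal transform (the per-residue winding) and the
#' translation component along the rotation axis (the rise per
#' residue).  Results are averaged over all window offsets; on an exact
#' mathematical helix every offset gives the same answer to machine
#' precision.
#'
#' @param calpha Numeric matrix (rows = ordered C-alpha positions,
#'   columns x, y, z), at least `window + 2` rows.
#' @param window Window length in residue steps (default 4, i.e. 5
#'   points per window, spanning more than one alpha-helical turn);
#'   must be >= 3.
#' @return List with `theta` (degrees per residue), `d` (rise per
#'   residue, Angstrom), `n` (= 360/theta).
#' @export
fit_screw_axis <- function(calpha, window = 4L) {
  calpha <- as.matrix(calpha)
  if (window < 3L) stop("window must be >= 3", call. = FALSE)
  m <- nrow(calpha)
  if (m < window + 2L)
    stop("need at least window + 2 C-alpha positions", call. = FALSE)
  if (qr(sweep(calpha, 2L, colMeans(calpha)))$rank < 2L)
    stop("degenerate axis: C-alpha positions are collinear", call. = FALSE)

  thetas <- rises <- numeric(0)
  for (i in seq_len(m - window - 1L)) {
    X <- calpha[i:(i + window), , drop = FALSE]
    Y <- calpha[(i + 1L):(i + window + 1L), , drop = FALSE]
    cx <- colMeans(X); cy <- colMeans(Y)
    Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
    sv <- svd(t(Xc) %*% Yc)
    dsign <- sign(det(sv$u %*% t(sv$v)))
    A <- sv$u %*% diag(c(1, 1, dsign)) %*% t(sv$v)  # row convention: y = x A
    R <- t(A)                                       # column convention
    ct <- (sum(diag(R)) - 1) / 2
    th <- acos(max(-1, min(1, ct)))
    if (sin(th) < 1e-9) next
    axis <- c(R[3L, 2L] - R[2L, 3L],
              R[1L, 3L] - R[3L, 1L],
              R[2L, 1L] - R[1L, 2L]) / (2 * sin(th))
    tr <- cy - as.vector(cx %*% A)
    thetas <- c(thetas, rad2deg(th))
    rises <- c(rises, abs(sum(tr * axis)))
  }
  if (!length(thetas))
    stop("degenerate transform: no rotation between windows", call. = FALSE)
  theta <- mean(thetas)
  list(theta = theta, d = mean(rises), n = 360 / theta)
}

# Convenience: C-alpha coordinate matrix of a structure's standard
# residues (caps excluded), in residue order.
calpha_matrix <- function(structure) {
  at <- structure$atoms
  sel <- at$name == "CA" & !is_cap(at$resname)
  as.matrix(at[sel, c("x", "y", "z"), drop = FALSE])
}

#' Dipole-dipole interaction energy
#'
#' The angular dependence of the interaction of two point dipoles,
#' V proportional to (cos theta12 - 3 cos theta1 cos theta2).  Two
#' forms are exposed: `"as_printed"` evaluates
#' V = -mu1 mu2 (cos theta12 - 3 cos theta1 cos theta2) with no
#' distance dependence, while `"textbook"` multiplies the angular
#' factor by +mu1 mu2 / r^3 (so the aligned head-to-tail arrangement,
#' all angles 0, gives the attractive -2 mu1 mu2 / r^3).  Minimising
#' either form over angles drives the arrangement collinear (alignment
#' at 0 or 180 degrees), the classical argument for why monopole
#' electrostatics favours linear hydrogen bonds.
#'
#' @param mu1,mu2 Dipole magnitudes (Debye; any consistent unit).
#' @param r Separation (Angstrom); ignored by `"as_printed"`.
#' @param theta1,theta2 Angles of each dipole to the inter-dipole axis,
#'   degrees.
#' @param theta12 Angle between the dipoles, degrees.
#' @param form `"as_printed"` (default) or `"textbook"`.
#' @return Energy (arbitrary units; mu1*mu2/r^3 units for textbook).
#' @export
dipole_interaction <- function(mu1, mu2, r = NA_real_,
                               theta1, theta2, theta12,
                               form = c("as_printed", "textbook")) {
  form <- match.arg(form)
  stopifnot(mu1 >= 0, mu2 >= 0)
  ang <- cos(deg2rad(theta12)) -
    3 * cos(deg2rad(theta1)) * cos(deg2rad(theta2))
  if (form == "as_printed") return(-mu1 * mu2 * ang)
  if (!is.finite(r) || r <= 0)
    stop("textbook form requires a positive separation r", call. = FALSE)
  mu1 * mu2 * ang / r^3
}
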