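# Low-level vector geometry shared by the builder, the interaction detectors and
# the superposition code. All coordinates are in Angstrom, all angles in degrees.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at vertex `b` of the triple a-b-c, in degrees.
#' @noRd
angle_deg <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  d <- max(-1, min(1, sum(u * v)))
  acos(d) * 180 / pi
}

#' Dihedral angle of the chain a-b-c-d, in degrees in (-180, 180].
#' @noRd
torsion_deg <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Place a new atom from internal coordinates (NeRF construction).
#'
#' Returns the position `d` such that |c-d| = bond, the angle b-c-d equals
#' `angle` and the dihedral a-b-c-d equals `torsion`.
#' @noRd
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + cbind(bc, m, n) %*% d2
}

#' Rotation matrix for a rotation of `theta` degrees about an axis.
#' @noRd
rotation_about <- function(axis, theta) {
  u <- vunit(axis)
  t <- theta * pi / 180
  ct <- cos(t); st <- sin(t)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

#' Kabsch least-squares superposition.
#'
#' Finds the proper rotation R and translation t minimising the RMSD between
#' `mobile %*% t(R) + t` and `reference` (both n x 3 matrices, row per atom).
#'
#' @return list(rotation, translation, rmsd) with x' = R x + t applied row-wise.
#' @noRd
kabsch <- function(mobile, reference) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (nrow(mobile) < 3)
    stop("degenerate fit: need at least 3 atoms in the selection")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  Pm <- sweep(mobile, 2, cm)
  Pr <- sweep(reference, 2, cr)
  # collinearity check: a well-posed fit needs rank >= 2 in the centred cloud
  sv <- svd(Pm)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate fit: selected atoms are (nearly) collinear")
  H <- crossprod(Pm, Pr)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Pm %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Pr)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

apply_transform <- function(coords, transform) {
  sweep(coords %*% t(transform$rotation), 2, transform$translation, `+`)
}

rmsd_value <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
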