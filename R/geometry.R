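# Small 3D geometry kernel: internal-coordinate atom placement (NeRF),
# bond/angle/dihedral measurement and rigid transforms.

#' @keywords internal
vnorm <- function(v) sqrt(sum(v^2))

#' @keywords internal
unit <- function(v) v / vnorm(v)

#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Returns the position of atom D given positions A, B, C, the bond length
#' C-D, the angle B-C-D and the dihedral A-B-C-D.
#'
#' @param a,b,c Numeric 3-vectors, positions of the three reference atoms.
#' @param bond Bond length C-D in Angstrom.
#' @param angle Angle B-C-D in degrees.
#' @param dihedral Dihedral A-B-C-D in degrees.
#' @return Numeric 3-vector, the position of D.
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(dih),
               -bond * sin(ang) * sin(dih))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Measure a dihedral angle
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Dihedral angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' @keywords internal
bond_angle <- function(p1, p2, p3) {
  v1 <- unit(p1 - p2)
  v2 <- unit(p3 - p2)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

#' Random proper rotation matrix
#' @keywords internal
random_rotation <- function() {
  repeat {
    m <- matrix(stats::rnorm(9), 3, 3)
    qr_m <- qr(m)
    q <- qr.Q(qr_m)
    d <- diag(sign(diag(qr.R(qr_m))))
    r <- q %*% d
    if (det(r) > 0) return(r)
  }
}

#' Apply a rigid transform to an n x 3 coordinate matrix
#' @keywords internal
rigid_transform <- function(xyz, rotation = diag(3), translation = c(0, 0, 0)) {
  sweep(xyz %*% t(rotation), 2, translation, `+`)
}

#' Evenly distributed unit sphere points (golden-spiral lattice)
#'
#' Deterministic point set used for numeric surface-area integration.
#' @keywords internal
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
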