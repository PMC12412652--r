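## Internal 3D geometry utilities shared by every structural module.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle defined by four points
#'
#' Signed torsion about the b--c axis, in degrees in (-180, 180].
#'
#' @param a,b,c,d Numeric 3-vectors (Cartesian coordinates, Angstrom).
#' @return Angle in degrees.
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

bond_angle <- function(a, b, c) {
  v1 <- unit(a - b)
  v2 <- unit(c - b)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

## NeRF atom placement: position a new atom given three predecessors,
## a bond length to `c`, an angle at `c` (with b), and a torsion a-b-c-new.
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180  # so that dihedral_angle(a, b, c, new) == torsion
  d2 <- c(length * cos(pi - ang),
          length * sin(pi - ang) * cos(tor),
          length * sin(pi - ang) * sin(tor))
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- cbind(bc, vcross(n, bc), n)
  as.numeric(m %*% d2 + c)
}

## Random proper rotation matrix (for tests and pose randomization).
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- vnorm(q)
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

## Apply rigid transform to an n x 3 coordinate matrix.
transform_xyz <- function(xyz, rotation, translation) {
  sweep(xyz %*% t(rotation), 2, translation, "+")
}

## Pairwise squared distances between two n x 3 matrices (vectorized).
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  outer(an, bn, "+") - 2 * (A %*% t(B))
}
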