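# Small 3D geometry helpers shared by the dihedral computation and the
# synthetic backbone builder.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

#' Dihedral angle of four points
#'
#' Torsion angle about the b-c axis following the IUPAC sign convention:
#' looking from b to c, a clockwise rotation of the far bond is positive.
#'
#' @param a,b,c,d numeric xyz coordinates (length 3)
#' @return angle in degrees in (-180, 180]
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- -sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Place a new atom D given three previous atoms A, B, C, the C-D bond length,
# the B-C-D bond angle (degrees) and the A-B-C-D torsion (degrees).
# Standard internal-coordinate (NeRF) construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- vcross(ab, bc)
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(rot %*% d2 + c)
}

# Pairwise Euclidean distance matrix between rows of two coordinate matrices.
cross_dist <- function(x, y) {
  xx <- rowSums(x^2)
  yy <- rowSums(y^2)
  d2 <- outer(xx, yy, "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

random_rotation_matrix <- function() {
  repeat {
    m <- matrix(stats::rnorm(9), 3, 3)
    qr_m <- qr(m)
    q <- qr.Q(qr_m)
    if (det(q) < 0) q[, 1] <- -q[, 1]
    if (abs(det(q) - 1) < 1e-8) return(q)
  }
}
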