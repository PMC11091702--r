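# Small geometry helpers shared across modules. All coordinates are in
# Angstrom; matrices of coordinates are n x 3 with atoms in rows.

#' @keywords internal
vnorm <- function(v) sqrt(sum(v^2))

#' @keywords internal
unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

#' Dihedral angle of four points
#'
#' Signed torsion a-b-c-d in degrees, in (-180, 180], using the standard
#' atan2 formulation. Used for endocyclic furanose torsions.
#'
#' @param a,b,c,d numeric 3-vectors (Angstrom).
#' @return angle in degrees.
#' @keywords internal
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# cross product (kept local; avoids pulling a dependency for one primitive)
#' @keywords internal
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Angle at vertex b of the triple a-b-c, in degrees
#' @keywords internal
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

#' Minimum distance between two coordinate sets
#' @keywords internal
min_cross_dist <- function(xa, xb) {
  xa <- rbind(xa)
  xb <- rbind(xb)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(max(0, min(d2)))
}

#' All pairwise distances between two coordinate sets
#' @keywords internal
cross_dist <- function(xa, xb) {
  xa <- rbind(xa)
  xb <- rbind(xb)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(pmax(d2, 0))
}

#' Apply a rigid-body transform to an n x 3 coordinate matrix
#' @keywords internal
apply_rigid <- function(x, rotation, translation = c(0, 0, 0)) {
  sweep(x %*% t(rotation), 2, -translation, "-")
}

#' Draw a random proper rotation matrix
#' @keywords internal
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
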