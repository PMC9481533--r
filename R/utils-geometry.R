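# Internal geometry helpers shared across modules.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# Rotation matrix for angle `deg` (degrees) about unit axis `u`
# (Rodrigues formula).
.rotationMatrix <- function(u, deg) {
  u <- .unit(u)
  th <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice,
# equal-area latitudes at golden-angle longitudes); no randomness so SASA
# results are bit-reproducible.
.spherePoints <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  theta <- acos(z)
  phi <- (k - 1) * pi * (3 - sqrt(5))
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), z)
}

# Dihedral angle (degrees) for points a-b-c-d.
.dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# NeRF placement: position atom D given A, B, C, bond |C-D|, angle B-C-D
# (degrees) and torsion A-B-C-D (degrees).
.placeAtom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- .unit(c - b)
  ab <- b - a
  nrm <- .unit(c(ab[2] * bc[3] - ab[3] * bc[2],
                 ab[3] * bc[1] - ab[1] * bc[3],
                 ab[1] * bc[2] - ab[2] * bc[1]))
  m <- cbind(bc, c(nrm[2] * bc[3] - nrm[3] * bc[2],
                   nrm[3] * bc[1] - nrm[1] * bc[3],
                   nrm[1] * bc[2] - nrm[2] * bc[1]), nrm)
  as.numeric(m %*% d2 + c)
}

# Least-squares plane normal of an n x 3 coordinate matrix.
.planeNormal <- function(xyz) {
  cen <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, cen))
  s$v[, 3]
}

# Rigid superposition (Kabsch): returns list(R, t) mapping `from` onto `onto`.
.kabsch <- function(from, onto) {
  cf <- colMeans(from); co <- colMeans(onto)
  H <- t(sweep(from, 2, cf)) %*% sweep(onto, 2, co)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = co - as.numeric(R %*% cf))
}
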