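# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

xprod <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Dihedral via explicit half-plane construction: project the outer bonds
# onto the plane perpendicular to the central bond and take the signed
# angle between the projections (sign from the scalar triple product).
oracle_dihedral <- function(p1, p2, p3, p4) {
  e <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  v1 <- (p1 - p2) - sum((p1 - p2) * e) * e
  v2 <- (p4 - p3) - sum((p4 - p3) * e) * e
  u1 <- v1 / sqrt(sum(v1^2))
  u2 <- v2 / sqrt(sum(v2^2))
  ang <- acos(max(-1, min(1, sum(u1 * u2)))) * 180 / pi
  # right-hand rotation of u1 onto u2 about e appears clockwise when
  # viewed from p2 towards p3, i.e. positive in the IUPAC convention
  if (sum(xprod(u1, u2) * e) >= 0) ang else -ang
}

# Horn's quaternion method for the optimal-superposition RMSD.
oracle_quaternion_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  M <- t(P0) %*% Q0
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P0^2) + sum(Q0^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

# Literal textbook operators of IT 146 in the hexagonal setting, written
# out as coordinate formulas rather than matrices.
oracle_h3_images <- function(fr) {
  x <- fr[1]; y <- fr[2]; z <- fr[3]
  rot <- list(c(x, y, z), c(-y, x - y, z), c(y - x, -x, z))
  cen <- list(c(0, 0, 0), c(2 / 3, 1 / 3, 1 / 3), c(1 / 3, 2 / 3, 2 / 3))
  out <- list()
  for (ct in cen) for (r in rot) out[[length(out) + 1]] <- r + ct
  out
}

# Brute-force symmetry-neighbour search by direct enumeration.
oracle_neighbors <- function(s, center, radius, shifts = -2:2) {
  cell <- structure_cell(s)
  a <- s$atom
  hits <- list()
  for (i in seq_len(nrow(a))) {
    fr <- as.vector(cell$frac %*% c(a$x[i], a$y[i], a$z[i]))
    for (img in oracle_h3_images(fr)) {
      for (sx in shifts) for (sy in shifts) for (sz in shifts) {
        p <- as.vector(cell$orth %*% (img + c(sx, sy, sz)))
        d <- sqrt(sum((p - center)^2))
        if (d <= radius)
          hits[[length(hits) + 1]] <- c(atom = i, d = d)
      }
    }
  }
  if (!length(hits)) return(data.frame(atom = integer(0), d = numeric(0)))
  out <- as.data.frame(do.call(rbind, hits))
  out[order(out$d), ]
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc - a * d), 2 * (b * d + a * cc),
           2 * (b * cc + a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d - a * b),
           2 * (b * d - a * cc), 2 * (cc * d + a * b), a^2 - b^2 - cc^2 + d^2),
         3, 3, byrow = TRUE)
}

# Four random points guaranteed non-degenerate for torsion measurement.
random_quad <- function() {
  repeat {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
    if (sqrt(sum(xprod(b1, b2)^2)) > 1e-3 &&
        sqrt(sum(xprod(b2, b3)^2)) > 1e-3)
      return(p)
  }
}

random_internal_chain <- function(n = sample(4:8, 1)) {
  internal_chain(paste0("A", seq_len(n)),
                 lengths = runif(n - 1, 1, 2.5),
                 angles = runif(n - 2, 30, 150),
                 dihedrals = runif(n - 3, -179, 180))
}
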