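# Exact vector geometry: distances, angles, torsions, chirality, and
# internal-coordinate <-> Cartesian conversion.

#' Angle at the central point of three positions
#'
#' @param p1,p2,p3 numeric length-3 coordinate vectors (Angstrom).
#' @return angle at \code{p2} in degrees, in [0, 180].
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- unit(p1 - p2)
  v <- unit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * DEG
}

#' Torsion angle of four positions (IUPAC sign convention)
#'
#' The dihedral about the p2--p3 bond: looking from \code{p2} towards
#' \code{p3}, a positive angle is a clockwise rotation carrying the
#' projection of p1--p2 onto the projection of p3--p4. Planar \emph{cis}
#' is 0 degrees and planar \emph{trans} is +180 degrees. The value is
#' antisymmetric under mirror reflection of the four points.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @examples
#' dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0)) # trans, 180
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("undefined dihedral: three consecutive points are collinear")
  ang <- atan2(sum(vcross(n1, n2) * b2) / vnorm(b2), sum(n1 * n2)) * DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Classify disulphide handedness from the chi3 torsion sign
#'
#' The Cb--Sg--Sg'--Cb' torsion of a disulphide bridge determines its
#' chirality: a positive chi3 (around +90 to +110 degrees in proteins) is
#' right-handed, a negative chi3 left-handed. An exactly zero torsion is
#' planar and carries no handedness.
#'
#' @param chi3 torsion angle in degrees.
#' @return \code{"right"} or \code{"left"}.
#' @examples
#' classify_handedness(108.23) # right
#' classify_handedness(-79.10) # left
#' @export
classify_handedness <- function(chi3) {
  stopifnot_scalar(chi3, "chi3")
  if (chi3 == 0) stop("ambiguous chirality: chi3 is exactly zero")
  if (chi3 > 0) "right" else "left"
}

#' Internal-coordinate description of an atom chain
#'
#' An n-atom chain is described by its n-1 bond lengths, n-2 bond angles
#' and n-3 torsions, in chain order.
#'
#' @param labels character atom labels, length n.
#' @param lengths bond lengths in Angstrom, length n-1, all positive.
#' @param angles bond angles in degrees, length n-2, each in (0, 180).
#' @param dihedrals torsions in degrees, length n-3, each in (-180, 180].
#' @return an object of class \code{internal_chain}.
#' @export
internal_chain <- function(labels, lengths, angles = numeric(0),
                           dihedrals = numeric(0)) {
  n <- length(labels)
  if (length(lengths) != n - 1 || length(angles) != max(0, n - 2) ||
      length(dihedrals) != max(0, n - 3))
    stop("internal_chain: need n-1 lengths, n-2 angles, n-3 dihedrals")
  if (any(lengths <= 0)) stop("internal_chain: bond lengths must be positive")
  if (length(angles) && any(angles <= 0 | angles >= 180))
    stop("internal_chain: bond angles must lie in (0, 180) degrees")
  if (length(dihedrals) && any(dihedrals <= -180 | dihedrals > 180))
    stop("internal_chain: dihedrals must lie in (-180, 180] degrees")
  structure(list(labels = labels, lengths = lengths, angles = angles,
                 dihedrals = dihedrals),
            class = "internal_chain")
}

#' @export
print.internal_chain <- function(x, ...) {
  cat("Internal chain:", paste(x$labels, collapse = "-"), "\n")
  cat("  lengths (A):", paste(sprintf("%.3f", x$lengths), collapse = ", "), "\n")
  if (length(x$angles))
    cat("  angles (deg):", paste(sprintf("%.2f", x$angles), collapse = ", "), "\n")
  if (length(x$dihedrals))
    cat("  torsions (deg):", paste(sprintf("%.2f", x$dihedrals), collapse = ", "), "\n")
  invisible(x)
}

# Place one atom at distance l from c, angle theta at c in the b-c
# direction, torsion phi about b->c relative to a (NeRF construction).
place_atom <- function(a, b, cc, l, theta, phi) {
  th <- theta / DEG
  ph <- phi / DEG
  if (abs(sin(th)) < 1e-10)
    stop("degenerate frame: bond angle of 0 or 180 degrees")
  bc <- unit(cc - b)
  n <- vcross(b - a, bc)
  if (vnorm(n) < 1e-10)
    stop("degenerate frame: reference atoms are collinear")
  n <- unit(n)
  m <- vcross(n, bc)
  d <- l * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  as.vector(cc + cbind(bc, m, n) %*% d)
}

#' Build Cartesian coordinates from internal coordinates
#'
#' Sequential (NeRF-style) placement: the first atom sits at the origin,
#' the second along +x, the third in the xy-plane, and every further atom
#' is placed at its stated bond length, bond angle and torsion from the
#' three preceding atoms. Measuring the result with
#' \code{\link{measure_internal}} reproduces the input to well below 1e-6.
#'
#' @param ic an \code{\link{internal_chain}}.
#' @return numeric matrix (n x 3) of coordinates in Angstrom, with the
#'   atom labels as row names.
#' @export
build_from_internal <- function(ic) {
  stopifnot(inherits(ic, "internal_chain"))
  n <- length(ic$labels)
  pos <- matrix(0, n, 3, dimnames = list(ic$labels, c("x", "y", "z")))
  if (n >= 2) pos[2, ] <- c(ic$lengths[1], 0, 0)
  if (n >= 3) {
    th <- ic$angles[1] / DEG
    if (abs(sin(th)) < 1e-10)
      stop("degenerate frame: bond angle of 0 or 180 degrees")
    pos[3, ] <- pos[2, ] + ic$lengths[2] * c(-cos(th), sin(th), 0)
  }
  if (n >= 4) {
    for (i in 4:n) {
      pos[i, ] <- place_atom(pos[i - 3, ], pos[i - 2, ], pos[i - 1, ],
                             ic$lengths[i - 1], ic$angles[i - 2],
                             ic$dihedrals[i - 3])
    }
  }
  pos
}

#' Measure the internal coordinates of a chain of positions
#'
#' The inverse of \code{\link{build_from_internal}}: all consecutive bond
#' lengths, bond angles and torsions of an ordered atom chain.
#'
#' @param positions numeric matrix (n x 3), n >= 2.
#' @param labels optional atom labels (defaults to row names or A1..An).
#' @return an \code{\link{internal_chain}}.
#' @export
measure_internal <- function(positions, labels = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("measure_internal: need at least two atoms")
  labels <- labels %||% rownames(positions) %||% paste0("A", seq_len(n))
  lengths <- vapply(seq_len(n - 1), function(i)
    vnorm(positions[i + 1, ] - positions[i, ]), numeric(1))
  angles <- if (n >= 3) vapply(seq_len(n - 2), function(i)
    bond_angle(positions[i, ], positions[i + 1, ], positions[i + 2, ]),
    numeric(1)) else numeric(0)
  dihedrals <- if (n >= 4) vapply(seq_len(n - 3), function(i)
    dihedral_angle(positions[i, ], positions[i + 1, ], positions[i + 2, ],
                   positions[i + 3, ]), numeric(1)) else numeric(0)
  internal_chain(labels, lengths, angles, dihedrals)
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the rotation and translation minimising the RMSD between selected
#' atoms of a mobile and a reference coordinate set, via the SVD of the
#' cross-covariance matrix with the usual determinant correction that
#' excludes improper rotations.
#'
#' @param mobile,reference numeric matrices (n x 3).
#' @param selection integer indices of the rows used for the fit
#'   (default: all). Both matrices use the same selection.
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3;
#'   the fitted mobile is \code{mobile \%*\% t(rotation) + translation}),
#'   \code{rmsd} (post-fit, Angstrom, over the selection) and
#'   \code{fitted} (the transformed full mobile set).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  sel <- selection %||% seq_len(nrow(mobile))
  if (length(sel) < 3) stop("kabsch_superpose: need at least 3 selected atoms")
  P <- mobile[sel, , drop = FALSE]
  Q <- reference[sel, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("kabsch_superpose: unequal selected atom counts")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp)
  Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  sv <- svd(H)
  if (sv$d[2] < 1e-12)
    stop("kabsch_superpose: degenerate (rank-deficient) atom spread")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cq - as.vector(R %*% cp)
  fit_sel <- P %*% t(R) + matrix(tr, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fit_sel - Q)^2)))
  fitted <- mobile %*% t(R) + matrix(tr, nrow(mobile), 3, byrow = TRUE)
  list(rotation = R, translation = tr, rmsd = rmsd, fitted = fitted)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b numeric matrices (n x 3) with matched rows.
#' @param superpose if \code{TRUE}, Kabsch-superpose \code{a} onto \code{b}
#'   first; otherwise compute the RMSD in place.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b, superpose = TRUE) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (superpose) {
    kabsch_superpose(a, b)$rmsd
  } else {
    sqrt(mean(rowSums((a - b)^2)))
  }
}
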