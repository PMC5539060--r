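# Unit-cell mathematics, rhombohedral space-group operators in the
# hexagonal setting, symmetry-mate neighbour searches and Matthews-volume
# bookkeeping.

#' Unit cell with orthogonalisation transforms
#'
#' @param a,b,c cell lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return object of class \code{unit_cell} with the cell volume
#'   (Angstrom^3) and the orthogonalisation (\code{orth}) and
#'   fractionalisation (\code{frac}) matrices in the standard PDB
#'   convention (a along x, b in the xy-plane).
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  for (v in list(a, b, c)) if (v <= 0) stop("cell lengths must be positive")
  for (v in list(alpha, beta, gamma))
    if (v <= 0 || v >= 180) stop("cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha / DEG); cb <- cos(beta / DEG); cg <- cos(gamma / DEG)
  sg <- sin(gamma / DEG)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) stop("impossible cell: metric is not positive definite")
  vfac <- sqrt(v2)
  orth <- matrix(c(a, b * cg, c * cb,
                   0, b * sg, c * (ca - cb * cg) / sg,
                   0, 0, c * vfac / sg),
                 3, 3, byrow = TRUE)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, volume = a * b * c * vfac,
                 orth = orth, frac = solve(orth)),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit_cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Unit cell from a structure's crystal record
#' @param s an \code{ultra_structure} with crystal information.
#' @return a \code{\link{unit_cell}}.
#' @export
structure_cell <- function(s) {
  if (is.null(s$crystal)) stop("structure carries no crystal information")
  cr <- s$crystal
  unit_cell(cr$a, cr$b, cr$c, cr$alpha, cr$beta, cr$gamma)
}

.sg_canonical <- function(name) {
  key <- toupper(gsub("[ :]", "", as.character(name)))
  if (key %in% c("P1", "1")) return("P1")
  if (key %in% c("H3", "R3H", "146", "R3")) return("H3")  # hexagonal setting
  NA_character_
}

#' Symmetry operators of a space group
#'
#' Supported groups: \code{P1} and the rhombohedral group IT 146 in its
#' hexagonal setting (named \code{"H3"}, \code{"R3:H"}, \code{"R 3"} or
#' \code{146}), whose 9 operators are the three-fold rotations
#' \{(x,y,z), (-y,x-y,z), (y-x,-x,z)\} combined with the rhombohedral
#' centering translations \{(0,0,0), (2/3,1/3,1/3), (1/3,2/3,2/3)\}.
#'
#' @param name space-group name (Hermann-Mauguin or IT number).
#' @return list of operators, each \code{list(R = 3x3 fractional rotation,
#'   t = fractional translation)}.
#' @export
spacegroup_ops <- function(name) {
  canon <- .sg_canonical(name)
  if (is.na(canon))
    stop(sprintf("unsupported space group '%s'; supported: P1, H3 (R3:H, 146)",
                 name))
  ident <- diag(3)
  if (canon == "P1")
    return(list(list(R = ident, t = c(0, 0, 0))))
  rots <- list(ident,
               matrix(c(0, -1, 0, 1, -1, 0, 0, 0, 1), 3, 3, byrow = TRUE),
               matrix(c(-1, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE))
  cents <- list(c(0, 0, 0), c(2 / 3, 1 / 3, 1 / 3), c(1 / 3, 2 / 3, 2 / 3))
  ops <- list()
  for (ct in cents) for (R in rots)
    ops[[length(ops) + 1]] <- list(R = R, t = ct)
  ops
}

.apply_op <- function(op, fr) {
  # fr: n x 3 fractional coordinates
  sweep(fr %*% t(op$R), 2, -op$t)
}

#' Atoms of all symmetry mates within a radius of a point
#'
#' Expands the asymmetric unit by every space-group operator and lattice
#' translations in a bounded shell, and returns each atom copy within
#' \code{radius} of \code{center}, tagged with its generating operator and
#' lattice shift. The identity mate (operator 1, zero shift) is included.
#'
#' @param s an \code{ultra_structure} with crystal information.
#' @param center orthogonal coordinates (length 3, Angstrom).
#' @param radius search radius in Angstrom.
#' @param shifts integer range of lattice translations searched along each
#'   cell axis (default -2:2, ample for radii up to a cell length).
#' @return data.frame with the atom row index (\code{atom}), operator
#'   index (\code{op}), lattice shift columns, mate coordinates, distance,
#'   and copied atom metadata.
#' @export
symmetry_neighbors <- function(s, center, radius, shifts = -2:2) {
  if (is.null(s$crystal)) stop("symmetry expansion requires crystal information")
  if (radius < 0) stop("radius must be non-negative")
  cell <- structure_cell(s)
  ops <- spacegroup_ops(s$crystal$space_group)
  a <- s$atom
  if (!nrow(a)) return(.empty_neighbors())
  xyz <- as.matrix(a[, c("x", "y", "z")])
  fr <- xyz %*% t(cell$frac)
  out <- vector("list", 0)
  grid <- expand.grid(sx = shifts, sy = shifts, sz = shifts)
  for (k in seq_along(ops)) {
    base <- .apply_op(ops[[k]], fr)
    for (g in seq_len(nrow(grid))) {
      sh <- as.numeric(grid[g, ])
      mate <- sweep(base, 2, -sh)
      ortho <- mate %*% t(cell$orth)
      d <- sqrt(colSums((t(ortho) - center)^2))
      hit <- which(d <= radius)
      if (length(hit)) {
        out[[length(out) + 1]] <- data.frame(
          atom = hit, op = k, sx = sh[1], sy = sh[2], sz = sh[3],
          x = ortho[hit, 1], y = ortho[hit, 2], z = ortho[hit, 3],
          dist = d[hit],
          chain = a$chain[hit], resno = a$resno[hit], resid = a$resid[hit],
          elety = a$elety[hit], alt = a$alt[hit], o = a$o[hit],
          category = a$category[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(.empty_neighbors())
  res <- do.call(rbind, out)
  res <- res[order(res$dist), ]
  rownames(res) <- NULL
  res
}

.empty_neighbors <- function() {
  data.frame(atom = integer(0), op = integer(0), sx = integer(0),
             sy = integer(0), sz = integer(0), x = numeric(0),
             y = numeric(0), z = numeric(0), dist = numeric(0),
             chain = character(0), resno = integer(0), resid = character(0),
             elety = character(0), alt = character(0), o = numeric(0),
             category = character(0), stringsAsFactors = FALSE)
}

#' Matthews coefficient and solvent fraction
#'
#' The Matthews volume V_M is the cell volume per Dalton of macromolecule:
#' V_cell / (n_ops * mass_per_asu). The solvent fraction uses the standard
#' convention 1 - 1.23/V_M, where 1.23 Angstrom^3/Da approximates the
#' specific volume of protein; it is a convention, not a fitted constant.
#'
#' @param cell a \code{\link{unit_cell}}.
#' @param n_ops number of symmetry operators (asymmetric units per cell).
#' @param mass_per_asu protein mass per asymmetric unit in Daltons.
#' @return list with \code{v_m} (Angstrom^3/Da) and \code{solvent_fraction}.
#' @export
matthews <- function(cell, n_ops, mass_per_asu) {
  stopifnot(inherits(cell, "unit_cell"))
  if (mass_per_asu <= 0) stop("mass per asymmetric unit must be positive")
  if (n_ops < 1) stop("n_ops must be at least 1")
  v_m <- cell$volume / (n_ops * mass_per_asu)
  list(v_m = v_m, solvent_fraction = 1 - 1.23 / v_m)
}
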