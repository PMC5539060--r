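# Deterministic generators of test structures with known ground truth:
# ideal helices and hairpins, disulphides at requested torsions with
# altloc splits, water networks with planted hydrogen-bond topology,
# metal sites on a crystallographic three-fold axis, multi-model
# trajectories, and a benchmark asymmetric-unit stand-in assembled from
# published bridge and salt-bridge geometry.

# Ideal backbone geometry used by all fixtures (Angstrom / degrees).
.BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            n_h = 1.010, ca_cb = 1.521,
            c_n_ca = 121.7, n_ca_c = 111.2, ca_c_n = 116.2, omega = 180)

.CANONICAL_PHIPSI <- list(alpha = c(-57, -47), three_ten = c(-49, -26),
                          pi = c(-60, -64), beta = c(-150, 140),
                          coil = c(-150, 60))

# Build an all-backbone peptide from per-residue torsions.
# Returns an atom data.frame with N, H, CA, CB, C, O per residue.
.build_peptide <- function(phi, psi, chain = "A", start_resno = 1,
                           resid = "ALA", origin = c(0, 0, 0),
                           add_h = TRUE, add_cb = TRUE) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  g <- .BB
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N; H <- N; CB <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  th <- g$n_ca_c / DEG
  C[1, ] <- CA[1, ] + g$ca_c * c(cos(pi - th), sin(pi - th), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], g$c_n,
                         g$ca_c_n, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], g$n_ca,
                          g$c_n_ca, g$omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], g$ca_c, g$n_ca_c,
                         phi[i])
  }
  for (i in seq_len(n)) {
    if (i < n) {
      u1 <- unit(CA[i, ] - C[i, ]); u2 <- unit(N[i + 1, ] - C[i, ])
      O[i, ] <- C[i, ] + g$c_o * -unit(u1 + u2)
    } else {
      # C-terminal carbonyl: in the CA-C plane, roughly trans to N-CA
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_o, 120.5, psi[i] %||% 180)
    }
    if (add_h && i > 1) {
      u1 <- unit(C[i - 1, ] - N[i, ]); u2 <- unit(CA[i, ] - N[i, ])
      H[i, ] <- N[i, ] + g$n_h * -unit(u1 + u2)
    }
    if (add_cb && resid != "GLY")
      CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ], g$ca_cb, 110.5, 122.5)
  }
  rows <- list()
  for (i in seq_len(n)) {
    at <- list(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ])
    if (add_h && i > 1) at$H <- H[i, ]
    if (add_cb && resid != "GLY") at$CB <- CB[i, ]
    for (nm in names(at)) {
      rows[[length(rows) + 1]] <- data.frame(
        elety = nm, resid = resid, chain = chain,
        resno = start_resno + i - 1,
        x = at[[nm]][1] + origin[1], y = at[[nm]][2] + origin[2],
        z = at[[nm]][3] + origin[3],
        elesy = substr(nm, 1, 1), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate an ideal helix
#'
#' Poly-alanine backbone at the canonical torsions of the requested helix
#' kind, with amide hydrogens placed so the helical main-chain hydrogen
#' bonds exist by construction (i to i+4 for alpha, i+3 for 3-10, i+5 for
#' pi). Optional coil flanks let assignment tests check exact spans.
#'
#' @param kind \code{"alpha"}, \code{"three_ten"} or \code{"pi"}.
#' @param n number of helical residues (>= 4; >= 6 recommended for pi).
#' @param flank integer length-2: coil residues before and after.
#' @param chain chain identifier.
#' @return an \code{ultra_structure}; the plan (kind and helical residue
#'   span) is in \code{attr(, "expected")}.
#' @export
make_helix <- function(kind = c("alpha", "three_ten", "pi"), n,
                       flank = c(0, 0), chain = "A") {
  kind <- match.arg(kind)
  if (n < 4) stop("a helix fixture needs at least 4 residues")
  pp <- .CANONICAL_PHIPSI[[kind]]
  coil <- .CANONICAL_PHIPSI$coil
  phi <- c(rep(coil[1], flank[1]), rep(pp[1], n), rep(coil[1], flank[2]))
  psi <- c(rep(coil[2], flank[1]), rep(pp[2], n), rep(coil[2], flank[2]))
  atom <- .build_peptide(phi, psi, chain = chain)
  s <- new_structure(atom, title = sprintf("ideal %s helix", kind))
  attr(s, "expected") <- list(
    kind = c(alpha = "alpha_helix", three_ten = "three_ten_helix",
             pi = "pi_turn")[[kind]],
    from = flank[1] + 1, to = flank[1] + n,
    offset = c(alpha = 4L, three_ten = 3L, pi = 5L)[[kind]])
  s
}

#' Generate an alpha-helix with one embedded pi-turn
#'
#' An alpha-helical run whose torsions switch to pi-helix values for one
#' turn, producing a single i to i+5 bond inside an otherwise i to i+4
#' pattern (the "looser turn" motif seen at helix midpoints).
#'
#' @param n_before,n_after alpha residues before and after the pi turn.
#' @param chain chain identifier.
#' @return an \code{ultra_structure} with the plan in
#'   \code{attr(, "expected")}.
#' @export
make_mixed_helix <- function(n_before = 6, n_after = 6, chain = "A") {
  a <- .CANONICAL_PHIPSI$alpha; p <- .CANONICAL_PHIPSI$pi
  n_pi <- 3  # one looser turn: enough widening for an i->i+5 bond
  phi <- c(rep(a[1], n_before), rep(p[1], n_pi), rep(a[1], n_after))
  psi <- c(rep(a[2], n_before), rep(p[2], n_pi), rep(a[2], n_after))
  s <- new_structure(.build_peptide(phi, psi, chain = chain),
                     title = "alpha helix with embedded pi turn")
  attr(s, "expected") <- list(kind = "alpha_helix", from = 1,
                              to = n_before + n_pi + n_after,
                              has_offset5 = TRUE)
  s
}

#' Generate a two-stranded antiparallel beta-hairpin
#'
#' Two extended strands joined by a four-residue reversal whose central
#' torsions sit inside the type-I-turn tolerance; the geometry yields the
#' turn's i to i+3 bond and at least two cross-strand main-chain bonds,
#' so strand, sheet and turn detection can be tested against the plan.
#'
#' @param n_strand residues per strand (default 5).
#' @param chain chain identifier.
#' @return an \code{ultra_structure} with the plan in
#'   \code{attr(, "expected")}.
#' @export
make_hairpin <- function(n_strand = 5, chain = "A") {
  b <- .CANONICAL_PHIPSI$beta
  turn <- list(c(-45, -35), c(-115, -5))  # within type-I tolerance
  phi <- c(rep(b[1], n_strand), turn[[1]][1], turn[[2]][1], rep(b[1], n_strand))
  psi <- c(rep(b[2], n_strand), turn[[1]][2], turn[[2]][2], rep(b[2], n_strand))
  s <- new_structure(.build_peptide(phi, psi, chain = chain),
                     title = "antiparallel beta hairpin")
  # terminal residues lack phi or psi, so the plan's strand extents start
  # and end one residue inside the chain
  attr(s, "expected") <- list(
    strand1 = c(2, n_strand), strand2 = c(n_strand + 3, 2 * n_strand + 1),
    turn = c(n_strand, n_strand + 3))
  s
}

.CYS_SS <- list(lengths = c(1.530, 1.810, 2.050, 1.810, 1.530),
                angles = c(114.0, 104.0, 104.0, 114.0),
                chi2 = -86, chi2p = -86)

# Build one Cys-Cys bridge's six atoms (CA,CB,SG | SG',CB',CA') from
# internal coordinates, returning the two residues' atom rows.
.ss_atoms <- function(chi3, lengths, angles, chi2, chi2p, chain, res1, res2,
                      alt = c("", ""), occ = c(1, 1), origin = c(0, 0, 0)) {
  ic <- internal_chain(c("CA", "CB", "SG", "SG'", "CB'", "CA'"),
                       lengths, angles, c(chi2, chi3, chi2p))
  pos <- build_from_internal(ic)
  pos <- sweep(pos, 2, -origin)
  mk <- function(nm, p, rn, al, oc) data.frame(
    elety = nm, resid = "CYS", chain = chain, resno = rn,
    x = p[1], y = p[2], z = p[3], alt = al, o = oc, b = 15,
    elesy = substr(nm, 1, 1), stringsAsFactors = FALSE)
  rbind(mk("CA", pos[1, ], res1, alt[1], occ[1]),
        mk("CB", pos[2, ], res1, alt[1], occ[1]),
        mk("SG", pos[3, ], res1, alt[1], occ[1]),
        mk("SG", pos[4, ], res2, alt[2], occ[2]),
        mk("CB", pos[5, ], res2, alt[2], occ[2]),
        mk("CA", pos[6, ], res2, alt[2], occ[2]))
}

#' Generate a disulphide bridge at a requested chi3 torsion
#'
#' Two cysteine residues with idealised covalent geometry (Cb-Sg 1.81,
#' Sg-Sg 2.05 Angstrom, tetrahedral-to-sulphur angles around 104-114
#' degrees) built at the requested central torsion. With
#' \code{altloc_split}, the second cysteine's SG/CB/CA are emitted in two
#' conformers A and B with the given occupancies and a separate chi3 for
#' B, emulating a bridge whose far sulphur occupies two sites.
#'
#' @param chi3 target Cb-Sg-Sg'-Cb' torsion (degrees, non-zero).
#' @param altloc_split optional list with \code{occ} (length-2, summing
#'   to 1) and \code{chi3_b} (torsion of the minor conformer).
#' @param chain,res1,res2 placement of the two cysteines.
#' @return an \code{ultra_structure}; \code{attr(, "expected")} carries
#'   the planted torsions and occupancies.
#' @export
make_disulphide <- function(chi3, altloc_split = NULL, chain = "A",
                            res1 = 6, res2 = 11) {
  if (chi3 == 0) stop("chi3 of exactly 0 has no defined handedness")
  p <- .CYS_SS
  if (is.null(altloc_split)) {
    atom <- .ss_atoms(chi3, p$lengths, p$angles, p$chi2, p$chi2p, chain,
                      res1, res2)
    expected <- list(chi3 = chi3, occ = 1)
  } else {
    occ <- altloc_split$occ
    if (abs(sum(occ) - 1) > 1e-6) stop("split occupancies must sum to 1")
    if (altloc_split$chi3_b == 0) stop("chi3 of exactly 0 has no defined handedness")
    a_rows <- .ss_atoms(chi3, p$lengths, p$angles, p$chi2, p$chi2p, chain,
                        res1, res2, alt = c("", "A"), occ = c(1, occ[1]))
    b_rows <- .ss_atoms(altloc_split$chi3_b, p$lengths, p$angles, p$chi2,
                        p$chi2p, chain, res1, res2, alt = c("", "B"),
                        occ = c(1, occ[2]))
    # conformer B shares the first cysteine's single site
    atom <- rbind(a_rows, b_rows[b_rows$alt == "B", ])
    expected <- list(chi3 = chi3, chi3_b = altloc_split$chi3_b, occ = occ)
  }
  s <- new_structure(atom, title = "synthetic disulphide")
  attr(s, "expected") <- expected
  s
}

# Candidate placement directions: octahedral axes first (pairwise >= 90
# degrees), then cube diagonals as fallbacks. Every placement is verified
# by explicit distance checks, so these are only proposals.
.DIRECTIONS <- local({
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  rbind(oct, unname(cube))
})

#' Generate a water network with planted hydrogen-bond topology
#'
#' Realises a declarative plan as coordinates: water-water edges (a
#' forest, or a single ring) are placed at bonding distance (2.8
#' Angstrom), and each water additionally receives the requested number
#' of serine-hydroxyl contacts at 2.7 Angstrom; everything else is kept
#' out of bonding range, so the census of the generated structure equals
#' the plan exactly.
#'
#' @param n_waters number of waters.
#' @param ww_edges two-column matrix of water index pairs (must form a
#'   forest), or \code{NULL}.
#' @param sc_counts integer vector (length \code{n_waters}) of side-chain
#'   contacts to plant per water.
#' @param ring if \code{TRUE}, ignore \code{ww_edges} and arrange all
#'   waters in a single ring.
#' @return an \code{ultra_structure}; \code{attr(, "expected")} holds the
#'   per-water (n_sc, n_ww) plan.
#' @export
make_water_network <- function(n_waters, ww_edges = NULL,
                               sc_counts = rep(0L, n_waters), ring = FALSE) {
  stopifnot(length(sc_counts) == n_waters)
  d_ww <- 2.8   # planted water-water bond length
  d_sc <- 2.7   # planted hydroxyl-water bond length
  min_sep <- 3.6  # anything not planted stays beyond the 3.4 A cutoff
  wpos <- matrix(NA_real_, n_waters, 3)
  if (ring) {
    if (n_waters < 3) stop("a ring needs at least 3 waters")
    r <- d_ww / (2 * sin(pi / n_waters))
    th <- 2 * pi * (seq_len(n_waters) - 1) / n_waters
    wpos <- cbind(r * cos(th), r * sin(th), 0)
    deg_ww <- rep(2L, n_waters)
  } else {
    deg_ww <- rep(0L, n_waters)
    adj <- vector("list", n_waters)
    if (!is.null(ww_edges) && nrow(ww_edges)) {
      for (e in seq_len(nrow(ww_edges))) {
        i <- ww_edges[e, 1]; j <- ww_edges[e, 2]
        adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
        deg_ww[i] <- deg_ww[i] + 1L; deg_ww[j] <- deg_ww[j] + 1L
      }
    }
    placed <- rep(FALSE, n_waters)
    comp_origin <- 0
    for (root in seq_len(n_waters)) {
      if (placed[root]) next
      wpos[root, ] <- c(comp_origin, 0, 0)
      placed[root] <- TRUE
      queue <- root
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        for (nb in adj[[cur]]) {
          if (placed[nb]) next
          ok <- FALSE
          for (di in seq_len(nrow(.DIRECTIONS))) {
            cand <- wpos[cur, ] + d_ww * .DIRECTIONS[di, ]
            others <- wpos[placed & seq_len(n_waters) != cur, , drop = FALSE]
            if (!nrow(others) ||
                min(sqrt(rowSums(sweep(others, 2, cand)^2))) > min_sep) {
              ok <- TRUE
              break
            }
          }
          if (!ok)
            stop("water plan not geometrically realisable: tree placement fails")
          wpos[nb, ] <- cand
          placed[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
      comp_origin <- comp_origin + 30
    }
  }
  rows <- list()
  for (i in seq_len(n_waters)) {
    rows[[length(rows) + 1]] <- data.frame(
      elety = "O", resid = "HOH", chain = "W", resno = 6000 + i,
      x = wpos[i, 1], y = wpos[i, 2], z = wpos[i, 3], elesy = "O",
      stringsAsFactors = FALSE)
  }
  # serine hydroxyl stubs: OG at bonding distance from its water, the
  # carbons behind it, everything kept clear of all other planted atoms
  ser_no <- 0
  stub_pos <- matrix(NA_real_, 0, 3)
  for (i in seq_len(n_waters)) {
    k <- sc_counts[i]
    if (!k) next
    picked <- 0
    for (di in seq_len(nrow(.DIRECTIONS))) {
      if (picked == k) break
      dv <- .DIRECTIONS[di, ]
      og <- wpos[i, ] + d_sc * dv
      far_w <- n_waters == 1 ||
        all(sqrt(rowSums(sweep(wpos[-i, , drop = FALSE], 2, og)^2)) > min_sep)
      far_og <- !nrow(stub_pos) ||
        all(sqrt(rowSums(sweep(stub_pos, 2, og)^2)) > min_sep)
      if (!far_w || !far_og) next
      picked <- picked + 1
      ser_no <- ser_no + 1
      stub_pos <- rbind(stub_pos, og)
      cb <- og + 1.4 * dv; ca <- og + 2.9 * dv
      rows[[length(rows) + 1]] <- data.frame(
        elety = c("OG", "CB", "CA"), resid = "SER", chain = "X",
        resno = ser_no,
        x = c(og[1], cb[1], ca[1]), y = c(og[2], cb[2], ca[2]),
        z = c(og[3], cb[3], ca[3]), elesy = c("O", "C", "C"),
        stringsAsFactors = FALSE)
    }
    if (picked < k)
      stop("water plan not geometrically realisable: side-chain stubs collide")
  }
  atom <- do.call(rbind, rows)
  s <- new_structure(atom, title = "synthetic water network")
  attr(s, "expected") <- data.frame(water = 6000 + seq_len(n_waters),
                                    n_sc = as.integer(sc_counts),
                                    n_ww = as.integer(deg_ww))
  s
}

.H3_CELL <- list(a = 81.827, b = 81.827, c = 33.849, alpha = 90, beta = 90,
                 gamma = 120, space_group = "H 3")

#' Generate a metal site on a crystallographic three-fold axis
#'
#' Places a Zn ion on the three-fold axis of a rhombohedral (hexagonal
#' setting) cell and one copy of each requested ligand at its stated
#' distance in the asymmetric unit, so symmetry expansion produces a
#' coordination sphere with multiplicity 3 per ligand.
#'
#' @param ligands list of lists with \code{resid}, \code{elety},
#'   \code{dist} (Angstrom) and \code{category}-defining residue name
#'   (e.g. HIS NE2, HOH O, ACT OXT).
#' @param cell crystal list (defaults to an 81.8 x 33.8 Angstrom H3 cell).
#' @param on_axis place the metal on the three-fold axis (default TRUE).
#' @return an \code{ultra_structure} with crystal information;
#'   \code{attr(, "expected")} holds the planted ligand distances.
#' @export
make_zn_site <- function(ligands = list(), cell = .H3_CELL, on_axis = TRUE) {
  uc <- unit_cell(cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma)
  zn_frac <- if (on_axis) c(0, 0, 0.3) else c(0.2, 0.1, 0.3)
  zn <- as.vector(uc$orth %*% zn_frac)
  rows <- list(data.frame(elety = "ZN", resid = "ZN", chain = "B",
                          resno = 2100, x = zn[1], y = zn[2], z = zn[3],
                          elesy = "ZN", stringsAsFactors = FALSE))
  # ligand directions tilted off the axis so the three mates are distinct
  base_dirs <- rbind(c(1, 0.3, 0.5), c(0.8, -0.5, -0.4), c(0.2, 1, 0.4),
                     c(-0.6, 0.7, -0.5))
  rn <- 2000
  for (k in seq_along(ligands)) {
    lg <- ligands[[k]]
    dv <- unit(base_dirs[(k - 1) %% nrow(base_dirs) + 1, ])
    p <- zn + lg$dist * dv
    rn <- rn + 10
    rows[[length(rows) + 1]] <- data.frame(
      elety = lg$elety, resid = lg$resid, chain = "B", resno = rn,
      x = p[1], y = p[2], z = p[3],
      elesy = .element_from_name(lg$elety), stringsAsFactors = FALSE)
  }
  atom <- do.call(rbind, rows)
  s <- new_structure(atom, crystal = cell, title = "synthetic Zn site")
  attr(s, "expected") <- list(
    distances = vapply(ligands, `[[`, numeric(1), "dist"),
    multiplicity = if (on_axis) 3L else 1L)
  s
}

#' Generate a multi-model trajectory from a schedule
#'
#' Frame i of the result realises the scheduled transforms exactly:
#' either a rigid-body motion of the whole structure, a per-frame target
#' value for one torsion (rotating a stated set of downstream atoms about
#' the torsion's central bond), or both.
#'
#' @param base a single-model \code{ultra_structure}.
#' @param n_frames number of models to emit.
#' @param rigid optional list with \code{axis} (unit vector),
#'   \code{angle_per_frame} (degrees) and \code{shift_per_frame}
#'   (Angstrom vector): frame i is the base rotated by (i-1) increments.
#' @param torsion optional list with \code{quad} (four atom specs as in
#'   \code{\link{torsion_series}}), \code{moving} (atom row indices to
#'   rotate) and \code{values} (length \code{n_frames} target angles).
#' @return a multi-model \code{ultra_structure}.
#' @export
make_trajectory <- function(base, n_frames, rigid = NULL, torsion = NULL) {
  stopifnot(inherits(base, "ultra_structure"), n_models(base) == 1)
  a <- base$atom
  nat <- nrow(a)
  base_xyz <- t(as.matrix(a[, c("x", "y", "z")]))  # 3 x n
  quad_idx <- NULL
  if (!is.null(torsion)) {
    quad_idx <- vapply(torsion$quad, function(q) .resolve_atom(base, q),
                       integer(1))
    if (length(torsion$values) != n_frames)
      stop("torsion schedule must provide one value per frame")
  }
  frames <- matrix(NA_real_, n_frames, 3 * nat)
  for (f in seq_len(n_frames)) {
    xyz <- base_xyz
    if (!is.null(torsion)) {
      p <- xyz[, quad_idx]
      cur <- dihedral_angle(p[, 1], p[, 2], p[, 3], p[, 4])
      delta <- (torsion$values[f] - cur) / DEG
      axis <- unit(p[, 3] - p[, 2])
      R <- .rotation_about(axis, delta)
      mv <- torsion$moving
      xyz[, mv] <- R %*% (xyz[, mv, drop = FALSE] - p[, 3]) + p[, 3]
    }
    if (!is.null(rigid)) {
      ang <- (f - 1) * (rigid$angle_per_frame %||% 0) / DEG
      R <- .rotation_about(unit(rigid$axis %||% c(0, 0, 1)), ang)
      sh <- (f - 1) * (rigid$shift_per_frame %||% c(0, 0, 0))
      xyz <- R %*% xyz + sh
    }
    frames[f, ] <- as.vector(xyz)
  }
  out <- base
  out$xyz <- frames
  out$atom$x <- frames[1, seq(1, 3 * nat, 3)]
  out$atom$y <- frames[1, seq(2, 3 * nat, 3)]
  out$atom$z <- frames[1, seq(3, 3 * nat, 3)]
  out
}

# Rodrigues rotation matrix about a unit axis by angle (radians).
.rotation_about <- function(axis, angle) {
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate a disorder-ledger fixture with planted classes
#'
#' An extended poly-alanine chain in which chosen positions are split
#' into two side-chain conformers (CB in altlocs A/B) or given planted
#' problems (missing CB, or an inflated side-chain B-factor).
#'
#' @param n chain length.
#' @param double_at,missing_at,high_b_at integer residue positions.
#' @param chain chain identifier.
#' @return an \code{ultra_structure}; \code{attr(, "expected")} holds the
#'   planted class labels.
#' @export
make_disorder_fixture <- function(n, double_at = integer(0),
                                  missing_at = integer(0),
                                  high_b_at = integer(0), chain = "A") {
  b <- .CANONICAL_PHIPSI$beta
  atom <- .build_peptide(rep(b[1], n), rep(b[2], n), chain = chain,
                         add_h = FALSE)
  atom$o <- 1; atom$b <- 10; atom$alt <- ""
  out <- list()
  for (i in seq_len(n)) {
    rows <- atom[atom$resno == i, ]
    if (i %in% missing_at) rows <- rows[rows$elety != "CB", ]
    if (i %in% high_b_at) rows$b[rows$elety == "CB"] <- 60
    if (i %in% double_at) {
      cb <- rows[rows$elety == "CB", ]
      cb_a <- cb; cb_a$alt <- "A"; cb_a$o <- 0.6
      cb_b <- cb; cb_b$alt <- "B"; cb_b$o <- 0.4
      cb_b$x <- cb_b$x + 1.2
      rows <- rbind(rows[rows$elety != "CB", ], cb_a, cb_b)
    }
    out[[i]] <- rows
  }
  s <- new_structure(do.call(rbind, out), title = "disorder fixture")
  labels <- rep("single_ordered", n)
  labels[missing_at] <- "problematic"
  labels[high_b_at] <- "problematic"
  labels[double_at] <- "double_conformer"
  attr(s, "expected") <- labels
  s
}
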