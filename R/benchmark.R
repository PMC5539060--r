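# A synthetic benchmark asymmetric unit assembled from published
# ultra-high-resolution insulin geometry: the three internal disulphide
# bridges with their printed internal coordinates (including the 80/20
# split of the chain-C bridge), the six salt-bridge contacts at their
# printed distances, and a Zn site on the crystallographic three-fold
# axis with His NE2 and acetate-oxygen ligands. It is a stand-in built
# entirely in code -- no deposited coordinates are shipped -- and exists
# so the full analysis pipeline can be exercised against known numbers.

# Printed internal coordinates of the three Cys6-Cys11 bridge conformers:
# chain A (single site), chain C major (altloc A, 80%) and minor (B, 20%).
.BRIDGE_GEOMETRY <- list(
  chainA = list(lengths = c(1.532, 1.797, 2.051, 1.806, 1.533),
                angles = c(116.37, 103.66, 101.86, 113.83),
                chi3 = 106.49),
  chainC_A = list(lengths = c(1.532, 1.815, 2.119, 1.785, 1.547),
                  angles = c(114.16, 98.05, 104.10, 112.22),
                  chi3 = 108.23),
  chainC_B = list(lengths = c(1.532, 1.815, 1.966, 1.771, 1.534),
                  angles = c(114.16, 112.79, 103.44, 114.26),
                  chi3 = -79.10))

# The six salt-bridge contacts: donor atom, acceptor atom, distance (A).
.BENCH_SALT_BRIDGES <- data.frame(
  donor_res = c("GLY", "ARG", "ARG", "LYS", "GLY", "ARG"),
  donor_chain = c("A", "B", "B", "B", "C", "D"),
  donor_resno = c(1, 22, 22, 29, 1, 22),
  donor_atom = c("H3", "HH11", "HH21", "NZ", "H3", "HH11"),
  acceptor_res = c("GLU", "GLU", "GLU", "THR", "GLU", "ASN"),
  acceptor_chain = c("A", "A", "A", "B", "C", "C"),
  acceptor_resno = c(4, 17, 17, 30, 4, 21),
  acceptor_atom = c("OE1", "OE2", "OE2", "OXT", "OE1", "O"),
  distance = c(1.94398, 2.25535, 2.59606, 2.4885, 1.79717, 2.52927),
  stringsAsFactors = FALSE)

.bench_atom <- function(elety, resid, chain, resno, p, alt = "", o = 1) {
  data.frame(elety = elety, resid = resid, chain = chain, resno = resno,
             x = p[1], y = p[2], z = p[3], alt = alt, o = o, b = 15,
             elesy = .element_from_name(elety), stringsAsFactors = FALSE)
}

# One amine-to-carboxylate island: the hydrogen (or bare N) placed at the
# printed distance along +x from the acceptor oxygen, every other polar
# atom kept out of contact range.
.bench_island_nterm <- function(chain, d, c0) {
  n <- c0 + c(d + 1.0, 0, 0)
  rbind(
    .bench_atom("N", "GLY", chain, 1, n),
    .bench_atom("H3", "GLY", chain, 1, c0 + c(d, 0, 0)),
    .bench_atom("H1", "GLY", chain, 1, n + c(0.5, 0.866, 0)),
    .bench_atom("H2", "GLY", chain, 1, n + c(0.5, -0.866, 0)),
    .bench_atom("CA", "GLY", chain, 1, n + c(0, 0, 1.46)),
    .bench_atom("OE1", "GLU", chain, 4, c0),
    .bench_atom("OE2", "GLU", chain, 4, c0 + c(-2.2, 0, 0)),
    .bench_atom("CD", "GLU", chain, 4, c0 + c(-1.1, 0.8, 0)))
}

.bench_island_arg <- function(d1, d2, c0) {
  u <- c(cos(50 / DEG), sin(50 / DEG), 0)
  rbind(
    .bench_atom("NH1", "ARG", "B", 22, c0 + c(d1 + 1.0, 0, 0)),
    .bench_atom("HH11", "ARG", "B", 22, c0 + c(d1, 0, 0)),
    .bench_atom("NH2", "ARG", "B", 22, c0 + (d2 + 1.0) * u),
    .bench_atom("HH21", "ARG", "B", 22, c0 + d2 * u),
    .bench_atom("OE2", "GLU", "A", 17, c0),
    .bench_atom("OE1", "GLU", "A", 17, c0 + c(-2.2, 0, 0)),
    .bench_atom("CD", "GLU", "A", 17, c0 + c(-1.1, -0.9, 0)))
}

.bench_island_lys <- function(d, c0) {
  rbind(
    .bench_atom("NZ", "LYS", "B", 29, c0 + c(d, 0, 0)),
    .bench_atom("CE", "LYS", "B", 29, c0 + c(d + 1.48, 0, 0)),
    .bench_atom("OXT", "THR", "B", 30, c0),
    .bench_atom("O", "THR", "B", 30, c0 + c(-2.2, 0, 0)),
    .bench_atom("CA", "THR", "B", 30, c0 + c(-1.1, 0.9, 0)))
}

.bench_island_argD <- function(d, c0) {
  rbind(
    .bench_atom("NH1", "ARG", "D", 22, c0 + c(d + 1.0, 0, 0)),
    .bench_atom("HH11", "ARG", "D", 22, c0 + c(d, 0, 0)),
    .bench_atom("O", "ASN", "C", 21, c0),
    .bench_atom("OXT", "ASN", "C", 21, c0 + c(-2.2, 0, 0)),
    .bench_atom("C", "ASN", "C", 21, c0 + c(-1.1, 0.9, 0)))
}

#' Synthetic benchmark asymmetric unit with published golden geometry
#'
#' Builds, entirely in code, a stand-in structure whose analysable
#' features reproduce published ultra-high-resolution insulin numbers:
#' the chain-A internal disulphide (chi3 = 106.49 deg), the chain-C
#' bridge split over two conformers (A: occupancy 0.80, Sg-Sg 2.119 A,
#' chi3 = 108.23 deg; B: occupancy 0.20, chi3 = -79.10 deg), the six
#' salt-bridge contacts at their printed distances, a C-terminal
#' threonine carboxylate, and a Zn ion on the three-fold axis of the
#' 81.827/33.849 Angstrom H3 cell coordinated by His NE2 (2.05 A) and an
#' acetate oxygen (2.00 A), each with symmetry multiplicity 3. This is a
#' reconstruction from printed values, not a deposited coordinate set.
#'
#' @return an \code{ultra_structure}; \code{attr(, "expected")} carries
#'   the planted golden numbers (bridge torsions and occupancies, the
#'   salt-bridge table, Zn ligand distances).
#' @export
synthetic_insulin_benchmark <- function() {
  sb <- .BENCH_SALT_BRIDGES
  parts <- list(
    .bench_island_nterm("A", sb$distance[1], c(12, 6, 5)),
    .bench_island_arg(sb$distance[2], sb$distance[3], c(28, 6, 5)),
    .bench_island_lys(sb$distance[4], c(12, 14, 5)),
    .bench_island_nterm("C", sb$distance[5], c(28, 14, 5)),
    .bench_island_argD(sb$distance[6], c(12, 22, 5)),
    # lone chain-A C-terminus, isolated
    rbind(.bench_atom("O", "ASN", "A", 21, c(28, 22, 5)),
          .bench_atom("OXT", "ASN", "A", 21, c(28, 22, 6.3)),
          .bench_atom("CA", "ASN", "A", 21, c(29.2, 22, 4.8))))
  # disulphide islands from the printed internal coordinates
  gA <- .BRIDGE_GEOMETRY$chainA
  parts[[length(parts) + 1]] <- .ss_atoms(
    gA$chi3, gA$lengths, gA$angles, .CYS_SS$chi2, .CYS_SS$chi2p,
    "A", 6, 11, origin = c(20, 6, 12))
  gCA <- .BRIDGE_GEOMETRY$chainC_A
  gCB <- .BRIDGE_GEOMETRY$chainC_B
  cA <- .ss_atoms(gCA$chi3, gCA$lengths, gCA$angles, .CYS_SS$chi2,
                  .CYS_SS$chi2p, "C", 6, 11, alt = c("", "A"),
                  occ = c(1, 0.80), origin = c(20, 14, 12))
  cB <- .ss_atoms(gCB$chi3, gCB$lengths, gCB$angles, .CYS_SS$chi2,
                  .CYS_SS$chi2p, "C", 6, 11, alt = c("", "B"),
                  occ = c(1, 0.20), origin = c(20, 14, 12))
  parts[[length(parts) + 1]] <- rbind(cA, cB[cB$alt == "B", ])
  # Zn site on the three-fold axis
  uc <- unit_cell(.H3_CELL$a, .H3_CELL$b, .H3_CELL$c, .H3_CELL$alpha,
                  .H3_CELL$beta, .H3_CELL$gamma)
  zn <- as.vector(uc$orth %*% c(0, 0, 0.3))
  d_ne2 <- unit(c(1, 0.3, 0.5)); d_act <- unit(c(0.8, -0.5, -0.4))
  parts[[length(parts) + 1]] <- rbind(
    .bench_atom("ZN", "ZN", "B", 2100, zn),
    .bench_atom("NE2", "HIS", "B", 10, zn + 2.05 * d_ne2),
    .bench_atom("CE1", "HIS", "B", 10, zn + 2.05 * d_ne2 + c(0, 0, 1.32)),
    .bench_atom("OXT", "ACT", "B", 2101, zn + 2.00 * d_act),
    .bench_atom("C", "ACT", "B", 2101, zn + 2.00 * d_act + c(0, 0, -1.25)))
  atom <- do.call(rbind, parts)
  atom <- atom[order(atom$chain, atom$resno, atom$alt, atom$elety), ]
  rownames(atom) <- NULL
  s <- new_structure(atom, crystal = .H3_CELL,
                     title = "synthetic insulin benchmark (reconstructed)")
  attr(s, "expected") <- list(
    chi3_chainA = gA$chi3, chi3_chainC_A = gCA$chi3,
    chi3_chainC_B = gCB$chi3, ss_chainC_A = gCA$lengths[3],
    occ_chainC = c(0.80, 0.20),
    salt_bridges = sb,
    zn_ligand_dist = c(NE2 = 2.05, OXT = 2.00))
  s
}
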