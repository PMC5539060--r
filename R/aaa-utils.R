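# Internal constants and small helpers shared across modules.

DEG <- 180 / pi

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")

.WATER_RES <- c("HOH", "WAT", "DOD", "H2O")

.METAL_RES <- c("ZN", "MG", "NA", "K", "CA", "MN", "FE", "CU", "NI", "CO",
                "CD", "HG", "LI", "SR", "CS", "BA")

# Expected heavy side-chain atoms per residue type (beyond N, CA, C, O).
.SIDECHAIN_ATOMS <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

.MAINCHAIN_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "HA", "HA2", "HA3",
                      "H1", "H2", "H3")

#' Normalise an atom name across PDB v3 and modelling-suite dialects
#'
#' Coordinate files and interaction tables in the literature use different
#' conventions for the same atom: the C-terminal carboxylate oxygens appear
#' as \code{OXT}/\code{O} (PDB v3) or \code{OT2}/\code{OT1}, and N-terminal
#' amine hydrogens as \code{H1}/\code{H2}/\code{H3} or
#' \code{H0A}/\code{H0B}/\code{H0C}. This maps any of these spellings onto
#' the PDB v3 name, which is the convention used internally everywhere.
#'
#' @param name character vector of atom names.
#' @return character vector of PDB v3 atom names.
#' @examples
#' normalize_atom_name(c("OT2", "H0C", "OXT"))
#' @export
normalize_atom_name <- function(name) {
  map <- c(OT1 = "O", OT2 = "OXT", H0A = "H1", H0B = "H2", H0C = "H3",
           HN = "H", O1 = "O", O2 = "OXT",
           HH1 = "HH11", HH2 = "HH21")
  out <- unname(ifelse(name %in% names(map), map[name], name))
  out
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  a / n
}

# Smallest circular difference between two angles in degrees, in [-180, 180].
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", what))
  invisible(x)
}
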