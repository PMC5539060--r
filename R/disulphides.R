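# Disulphide-bridge enumeration across conformers and full
# internal-coordinate geometry reporting with handedness.

#' Find disulphide bridges, one per compatible conformer combination
#'
#' All pairs of cysteine Sg atoms within \code{ss_max} are reported.
#' Conformers pair when their altloc labels are identical, or when one of
#' them is blank (a split cysteine bonded to a single-site partner yields
#' one bridge per split conformer, as for an 80/20 Sg). Each bridge
#' carries the minimum occupancy of its two sulphurs and the full
#' Ca-Cb-Sg-Sg'-Cb'-Ca' internal geometry, including the central chi3
#' torsion and its handedness.
#'
#' @param s an \code{ultra_structure}.
#' @param ss_max maximum Sg-Sg separation (Angstrom, default 2.5).
#' @return list of \code{disulphide_bridge} objects, each with fields
#'   \code{cys1}, \code{cys2} (chain/resno/altloc), \code{occupancy},
#'   \code{geometry} (an \code{\link{internal_chain}}), \code{chi3},
#'   \code{handedness}.
#' @export
find_disulphides <- function(s, ss_max = 2.5) {
  a <- s$atom
  sg <- which(a$resid == "CYS" & normalize_atom_name(a$elety) == "SG")
  out <- list()
  if (length(sg) < 2) return(out)
  for (i in seq_along(sg)) {
    for (j in seq_along(sg)) {
      if (j <= i) next
      i1 <- sg[i]; i2 <- sg[j]
      same_res <- a$chain[i1] == a$chain[i2] && a$resno[i1] == a$resno[i2]
      if (same_res) next
      if (!.altloc_compatible(a$alt[i1], a$alt[i2])) next
      d <- sqrt((a$x[i1] - a$x[i2])^2 + (a$y[i1] - a$y[i2])^2 +
                  (a$z[i1] - a$z[i2])^2)
      if (d > ss_max) next
      b <- .make_bridge(s, i1, i2)
      if (!is.null(b)) out[[length(out) + 1]] <- b
    }
  }
  # stable order: by chain/resno of first partner, then altloc
  if (length(out)) {
    ord <- order(vapply(out, function(b)
      sprintf("%s%04d%s%04d%s", b$cys1$chain, b$cys1$resno, b$cys2$chain,
              b$cys2$resno, paste0(b$cys1$alt, b$cys2$alt)), character(1)))
    out <- out[ord]
  }
  out
}

# pick a named atom of the residue owning row `ref`, preferring the
# conformer label of `ref`, falling back to blank
.res_atom <- function(a, ref, nm) {
  rows <- which(a$chain == a$chain[ref] & a$resno == a$resno[ref] &
                  a$insert == a$insert[ref] &
                  normalize_atom_name(a$elety) == nm)
  if (!length(rows)) return(NA_integer_)
  lab <- rows[a$alt[rows] == a$alt[ref]]
  if (length(lab)) return(lab[1])
  blank <- rows[a$alt[rows] == ""]
  if (length(blank)) return(blank[1])
  NA_integer_
}

.make_bridge <- function(s, sg1, sg2) {
  a <- s$atom
  ca1 <- .res_atom(a, sg1, "CA"); cb1 <- .res_atom(a, sg1, "CB")
  ca2 <- .res_atom(a, sg2, "CA"); cb2 <- .res_atom(a, sg2, "CB")
  if (anyNA(c(ca1, cb1, ca2, cb2))) {
    warning(sprintf("cysteine %s%d or %s%d missing CA/CB; bridge skipped",
                    a$chain[sg1], a$resno[sg1], a$chain[sg2], a$resno[sg2]))
    return(NULL)
  }
  idx <- c(ca1, cb1, sg1, sg2, cb2, ca2)
  pos <- as.matrix(a[idx, c("x", "y", "z")])
  labels <- c("CA", "CB", "SG", "SG'", "CB'", "CA'")
  geom <- measure_internal(pos, labels)
  chi3 <- geom$dihedrals[2]  # CB-SG-SG'-CB'
  structure(list(
    cys1 = list(chain = a$chain[sg1], resno = a$resno[sg1], alt = a$alt[sg1]),
    cys2 = list(chain = a$chain[sg2], resno = a$resno[sg2], alt = a$alt[sg2]),
    intra_chain = a$chain[sg1] == a$chain[sg2],
    occupancy = min(a$o[sg1], a$o[sg2]),
    geometry = geom,
    chi3 = chi3,
    handedness = classify_handedness(chi3)),
    class = "disulphide_bridge")
}

#' @export
print.disulphide_bridge <- function(x, ...) {
  cat(geometry_report(x), sep = "\n")
  invisible(x)
}

#' Formatted geometry record of a disulphide bridge
#'
#' All bond lengths (Angstrom), bond angles and the chi3 torsion (degrees)
#' of the Ca-Cb-Sg-Sg'-Cb'-Ca' chain, in chain order, with the handedness
#' label.
#'
#' @param b a \code{disulphide_bridge}.
#' @return character vector of report lines.
#' @export
geometry_report <- function(b) {
  stopifnot(inherits(b, "disulphide_bridge"))
  g <- b$geometry
  lab1 <- sprintf("Cys%s%d%s", b$cys1$chain, b$cys1$resno,
                  ifelse(b$cys1$alt == "", "", paste0("(", b$cys1$alt, ")")))
  lab2 <- sprintf("Cys%s%d%s", b$cys2$chain, b$cys2$resno,
                  ifelse(b$cys2$alt == "", "", paste0("(", b$cys2$alt, ")")))
  lens <- sprintf("%s-%s = %.3f A",
                  g$labels[-length(g$labels)], g$labels[-1], g$lengths)
  angs <- sprintf("%s-%s-%s = %.2f deg",
                  g$labels[1:4], g$labels[2:5], g$labels[3:6], g$angles)
  c(sprintf("Disulphide %s - %s (occupancy %.2f)", lab1, lab2, b$occupancy),
    paste(" ", lens), paste(" ", angs),
    sprintf("  chi3 (CB-SG-SG'-CB') = %.2f deg, %s-handed",
            b$chi3, b$handedness))
}

#' Summarise disulphide bridges as a table
#' @param bridges list from \code{\link{find_disulphides}}.
#' @return data.frame with one row per conformer bridge.
#' @export
disulphide_table <- function(bridges) {
  if (!length(bridges)) {
    return(data.frame(chain1 = character(0), resno1 = integer(0),
                      alt1 = character(0), chain2 = character(0),
                      resno2 = integer(0), alt2 = character(0),
                      ss_length = numeric(0), chi3 = numeric(0),
                      handedness = character(0), occupancy = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(bridges, function(b) data.frame(
    chain1 = b$cys1$chain, resno1 = b$cys1$resno, alt1 = b$cys1$alt,
    chain2 = b$cys2$chain, resno2 = b$cys2$resno, alt2 = b$cys2$alt,
    ss_length = b$geometry$lengths[3], chi3 = b$chi3,
    handedness = b$handedness, occupancy = b$occupancy,
    stringsAsFactors = FALSE)))
}
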