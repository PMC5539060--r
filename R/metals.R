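# Metal coordination spheres via crystallographic symmetry expansion.

#' Find metal coordination sites
#'
#' For every metal atom, collects all ligand atoms (N, O, S donors of
#' protein side chains, waters and small molecules) within \code{cutoff},
#' expanding symmetry mates when crystal information is present (a metal
#' on a special position such as the three-fold axis then receives its
#' complete coordination sphere, e.g. three symmetry-related His NE2
#' atoms from one copy in the asymmetric unit). Symmetry-equivalent
#' ligands generated by the site's rotations are collapsed to one
#' representative with a multiplicity.
#'
#' @param s an \code{ultra_structure}.
#' @param cutoff coordination distance cutoff (Angstrom, default 2.8).
#' @param self_exclude radius (Angstrom) inside which mates of the metal
#'   itself are discarded (special-position images at ~0 distance).
#' @return list of \code{metal_site} objects with \code{metal},
#'   \code{ligands} (data.frame with distance, generating op, class and
#'   multiplicity) and \code{coordination} (total ligand count, counting
#'   multiplicity).
#' @export
find_metal_sites <- function(s, cutoff = 2.8, self_exclude = 0.2) {
  a <- s$atom
  metals <- which(a$category == "metal")
  out <- list()
  use_sym <- !is.null(s$crystal)
  if (!use_sym && length(metals))
    warning("no crystal information: coordination restricted to the asymmetric unit")
  for (m in metals) {
    center <- c(a$x[m], a$y[m], a$z[m])
    if (use_sym) {
      nb <- symmetry_neighbors(s, center, cutoff)
    } else {
      d <- sqrt((a$x - center[1])^2 + (a$y - center[2])^2 +
                  (a$z - center[3])^2)
      hit <- which(d <= cutoff)
      nb <- data.frame(atom = hit, op = 1L, sx = 0L, sy = 0L, sz = 0L,
                       x = a$x[hit], y = a$y[hit], z = a$z[hit],
                       dist = d[hit], chain = a$chain[hit],
                       resno = a$resno[hit], resid = a$resid[hit],
                       elety = a$elety[hit], alt = a$alt[hit],
                       o = a$o[hit], category = a$category[hit],
                       stringsAsFactors = FALSE)
    }
    # drop the metal itself and its special-position images
    nb <- nb[!(nb$atom == m & nb$dist <= self_exclude), , drop = FALSE]
    # only plausible coordinating elements
    elem <- .element_from_name(nb$elety)
    nb <- nb[elem %in% c("N", "O", "S", "CL", "BR"), , drop = FALSE]
    nb <- nb[nb$category != "metal", , drop = FALSE]
    if (nrow(nb)) {
      nb$class <- c(polymer = "protein-sidechain", water = "water",
                    ligand = "small-molecule")[nb$category]
      key <- paste(nb$chain, nb$resno, nb$elety, nb$alt)
      agg <- lapply(split(seq_len(nrow(nb)), key), function(ii) {
        first <- ii[which.min(nb$dist[ii])]
        cbind(nb[first, c("atom", "chain", "resno", "resid", "elety", "alt",
                          "dist", "class"), drop = FALSE],
              multiplicity = length(ii))
      })
      lig <- do.call(rbind, agg)
      lig <- lig[order(lig$dist), ]
      rownames(lig) <- NULL
    } else {
      lig <- data.frame(atom = integer(0), chain = character(0),
                        resno = integer(0), resid = character(0),
                        elety = character(0), alt = character(0),
                        dist = numeric(0), class = character(0),
                        multiplicity = integer(0), stringsAsFactors = FALSE)
    }
    site <- structure(list(
      metal = list(row = m, resid = a$resid[m], chain = a$chain[m],
                   resno = a$resno[m], elety = a$elety[m]),
      ligands = lig,
      coordination = sum(lig$multiplicity),
      flagged = nrow(lig) == 0), class = "metal_site")
    out[[length(out) + 1]] <- site
  }
  out
}

#' @export
print.metal_site <- function(x, ...) {
  cat(sprintf("metal_site: %s %s%d (%s), coordination %d%s\n",
              x$metal$resid, x$metal$chain %||% "?", x$metal$resno,
              x$metal$elety, x$coordination,
              if (x$flagged) " [no ligands within cutoff]" else ""))
  if (nrow(x$ligands)) print(x$ligands[, c("chain", "resno", "resid",
                                           "elety", "dist", "class",
                                           "multiplicity")])
  invisible(x)
}
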