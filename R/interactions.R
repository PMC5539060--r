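# Geometric hydrogen-bond detection, the water-network census,
# residues-without-water reporting and salt-bridge detection.

#' Geometric hydrogen-bond criteria
#'
#' Defaults follow common geometric practice: donor-acceptor heavy-atom
#' distance at most 3.4 Angstrom, hydrogen-acceptor distance at most 2.5
#' Angstrom and donor-H-acceptor angle at least 120 degrees. When
#' hydrogens are absent from a donor the heavy-atom distance alone
#' decides.
#'
#' @param max_da donor-acceptor heavy-atom cutoff (Angstrom).
#' @param max_ha hydrogen-acceptor cutoff (Angstrom).
#' @param min_dha minimum donor-H-acceptor angle (degrees).
#' @param use_hydrogens apply the H-based criteria where hydrogens exist.
#' @return list of class \code{hbond_criteria}.
#' @export
hbond_criteria <- function(max_da = 3.4, max_ha = 2.5, min_dha = 120,
                           use_hydrogens = TRUE) {
  if (max_da <= 0 || max_ha <= 0) stop("distance cutoffs must be positive")
  if (min_dha < 0 || min_dha > 180) stop("min_dha must lie in [0, 180]")
  structure(list(max_da = max_da, max_ha = max_ha, min_dha = min_dha,
                 use_hydrogens = isTRUE(use_hydrogens)),
            class = "hbond_criteria")
}

# Interaction group of each atom: W (water), SC (side chain, including the
# charged terminal amine and carboxylate groups), MC (main chain), LIG, MET.
.atom_groups <- function(a) {
  grp <- rep("LIG", nrow(a))
  grp[a$category == "water"] <- "W"
  grp[a$category == "metal"] <- "MET"
  poly <- a$category == "polymer"
  name <- normalize_atom_name(a$elety)
  grp[poly] <- ifelse(name[poly] %in% .MAINCHAIN_ATOMS, "MC", "SC")
  # terminal groups count as interacting side-chain groups
  for (ch in unique(a$chain[poly])) {
    rows <- which(poly & a$chain == ch)
    rn <- a$resno[rows]
    first <- rows[rn == min(rn)]
    last <- rows[rn == max(rn)]
    grp[first[name[first] %in% c("N", "H1", "H2", "H3")]] <- "SC"
    grp[last[name[last] %in% c("O", "OXT")]] <- "SC"
  }
  grp
}

# Map each hydrogen row to its parent heavy-atom row (same residue,
# compatible altloc, nearest within 1.3 A); NA when unattached.
.h_parents <- function(a) {
  parent <- rep(NA_integer_, nrow(a))
  hy <- which(a$elesy == "H")
  if (!length(hy)) return(parent)
  heavy <- which(a$elesy != "H")
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  heavy_by_res <- split(heavy, key[heavy])
  for (i in hy) {
    cand <- heavy_by_res[[key[i]]]
    cand <- cand[a$alt[cand] == "" | a$alt[i] == "" | a$alt[cand] == a$alt[i]]
    if (!length(cand)) next
    d <- sqrt((a$x[cand] - a$x[i])^2 + (a$y[cand] - a$y[i])^2 +
                (a$z[cand] - a$z[i])^2)
    j <- which.min(d)
    if (d[j] <= 1.3) parent[i] <- cand[j]
  }
  parent
}

.DONOR_NAMES <- c("N", "NZ", "NE", "NH1", "NH2", "ND1", "NE2", "ND2", "NE1",
                  "OG", "OG1", "OH", "SG", "OXT")

.altloc_compatible <- function(a1, a2) a1 == "" | a2 == "" | a1 == a2

#' Detect hydrogen bonds in a structure
#'
#' Every donor/acceptor atom pair satisfying the geometric criteria, each
#' reported once. Donors are polar atoms carrying a hydrogen; polar atoms
#' whose hydrogens are not present in the model (waters refined without H,
#' hydroxyls) fall back to the heavy-atom distance criterion. Acceptors
#' are oxygen atoms. Interactions are only formed between conformers with
#' matching or blank altloc labels, and each bond carries the limiting
#' occupancy of its partners.
#'
#' @param s an \code{ultra_structure}.
#' @param criteria an \code{\link{hbond_criteria}}.
#' @return data.frame of bonds ordered by donor and acceptor serial:
#'   donor/acceptor row indices and labels, optional hydrogen, distances
#'   \code{d_da}, \code{d_ha}, angle \code{angle_dha}, interaction
#'   \code{class} (e.g. \code{"SC-W"}, \code{"W-W"}) and \code{occupancy}.
#' @export
find_hbonds <- function(s, criteria = hbond_criteria()) {
  stopifnot(inherits(s, "ultra_structure"), inherits(criteria, "hbond_criteria"))
  a <- s$atom
  if (!nrow(a)) return(.empty_hbonds())
  grp <- .atom_groups(a)
  name <- normalize_atom_name(a$elety)
  parents <- .h_parents(a)
  any_h <- any(a$elesy == "H")
  use_h <- criteria$use_hydrogens && any_h
  if (criteria$use_hydrogens && !any_h)
    warning("no hydrogens present; falling back to heavy-atom criterion")

  heavy <- a$elesy != "H"
  donor_ok <- heavy & (a$elesy %in% c("N", "O", "S")) &
    (name %in% .DONOR_NAMES | a$category == "water")
  acc_ok <- heavy & a$elesy == "O"
  don_idx <- which(donor_ok)
  acc_idx <- which(acc_ok)
  if (!length(don_idx) || !length(acc_idx)) return(.empty_hbonds())

  # hydrogens attached to each donor
  h_of <- split(which(!is.na(parents)), parents[!is.na(parents)])

  xyz <- as.matrix(a[, c("x", "y", "z")])
  dd <- xyz[don_idx, , drop = FALSE]
  aa <- xyz[acc_idx, , drop = FALSE]
  d2 <- outer(rowSums(dd^2), rep(1, nrow(aa))) +
    outer(rep(1, nrow(dd)), rowSums(aa^2)) - 2 * dd %*% t(aa)
  d2[d2 < 0] <- 0
  within <- which(d2 <= criteria$max_da^2, arr.ind = TRUE)
  if (!nrow(within)) return(.empty_hbonds())

  res_key <- paste(a$chain, a$resno, a$insert, sep = "|")
  rows <- vector("list", nrow(within))
  for (r in seq_len(nrow(within))) {
    di <- don_idx[within[r, 1]]
    ai <- acc_idx[within[r, 2]]
    if (di == ai) next
    if (res_key[di] == res_key[ai]) next
    if (!.altloc_compatible(a$alt[di], a$alt[ai])) next
    d_da <- sqrt(d2[within[r, 1], within[r, 2]])
    hyd <- h_of[[as.character(di)]]
    h_sel <- NA_integer_
    d_ha <- NA_real_
    ang <- NA_real_
    if (use_h && !length(hyd) && a$elesy[di] == "N") next
    if (use_h && length(hyd)) {
      hh <- hyd[.altloc_compatible(a$alt[hyd], a$alt[ai])]
      if (!length(hh)) next
      dh <- sqrt((a$x[hh] - a$x[ai])^2 + (a$y[hh] - a$y[ai])^2 +
                   (a$z[hh] - a$z[ai])^2)
      angs <- vapply(seq_along(hh), function(q)
        bond_angle(xyz[di, ], xyz[hh[q], ], xyz[ai, ]), numeric(1))
      pass <- dh <= criteria$max_ha & angs >= criteria$min_dha
      if (!any(pass)) next
      best <- which(pass)[which.min(dh[pass])]
      h_sel <- hh[best]
      d_ha <- dh[best]
      ang <- angs[best]
    }
    rows[[r]] <- data.frame(
      donor = di, hydrogen = h_sel, acceptor = ai,
      d_da = d_da, d_ha = d_ha, angle_dha = ang, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.empty_hbonds())
  bonds <- do.call(rbind, rows)
  # one record per unordered atom pair
  pk <- paste(pmin(bonds$donor, bonds$acceptor),
              pmax(bonds$donor, bonds$acceptor))
  bonds <- bonds[order(pk, is.na(bonds$hydrogen), bonds$d_ha), ]
  bonds <- bonds[!duplicated(paste(pmin(bonds$donor, bonds$acceptor),
                                   pmax(bonds$donor, bonds$acceptor))), ]
  g1 <- grp[bonds$donor]
  g2 <- grp[bonds$acceptor]
  bonds$class <- vapply(seq_len(nrow(bonds)), function(i)
    paste(sort(c(g1[i], g2[i]), decreasing = TRUE), collapse = "-"),
    character(1))
  bonds$donor_label <- .atom_label(a, bonds$donor)
  bonds$acceptor_label <- .atom_label(a, bonds$acceptor)
  bonds$occupancy <- pmin(a$o[bonds$donor], a$o[bonds$acceptor])
  bonds <- bonds[order(bonds$donor, bonds$acceptor), ]
  rownames(bonds) <- NULL
  bonds
}

.atom_label <- function(a, idx) {
  sprintf("%s%s%d:%s", a$resid[idx], a$chain[idx], a$resno[idx], a$elety[idx])
}

.empty_hbonds <- function() {
  data.frame(donor = integer(0), hydrogen = integer(0), acceptor = integer(0),
             d_da = numeric(0), d_ha = numeric(0), angle_dha = numeric(0),
             class = character(0), donor_label = character(0),
             acceptor_label = character(0), occupancy = numeric(0),
             stringsAsFactors = FALSE)
}

#' Water hydrogen-bond census
#'
#' Types every water by its number of side-chain and water-water hydrogen
#' bonds and tabulates the (n_SC, n_WW) matrix, together with the totals:
#' unique side-chain-water bonds, unique water-water bonds, and waters
#' with no hydrogen bonds at all.
#'
#' @param bonds output of \code{\link{find_hbonds}} on \code{s}.
#' @param s the structure the bonds were computed on.
#' @return object of class \code{water_census}: list with \code{matrix}
#'   (data.frame n_sc, n_ww, n), \code{per_water}, \code{total_sc_w},
#'   \code{total_w_w}, \code{isolated}, \code{n_waters}.
#' @export
water_census <- function(bonds, s) {
  a <- s$atom
  wat_rows <- which(a$category == "water")
  wat_key <- unique(paste(a$chain, a$resno, a$insert, sep = "|")[wat_rows])
  if (!length(wat_key)) {
    return(structure(list(
      matrix = data.frame(n_sc = integer(0), n_ww = integer(0),
                          n = integer(0)),
      per_water = data.frame(water = character(0), n_sc = integer(0),
                             n_ww = integer(0), n_bonds = integer(0)),
      total_sc_w = 0, total_w_w = 0, isolated = 0L, n_waters = 0L),
      class = "water_census"))
  }
  res_key <- paste(a$chain, a$resno, a$insert, sep = "|")
  n_sc <- stats::setNames(rep(0L, length(wat_key)), wat_key)
  n_ww <- n_sc
  n_any <- n_sc
  for (i in seq_len(nrow(bonds))) {
    di <- bonds$donor[i]
    ai <- bonds$acceptor[i]
    dw <- a$category[di] == "water"
    aw <- a$category[ai] == "water"
    cls <- bonds$class[i]
    if (dw) n_any[res_key[di]] <- n_any[res_key[di]] + 1L
    if (aw) n_any[res_key[ai]] <- n_any[res_key[ai]] + 1L
    if (cls == "W-W") {
      n_ww[res_key[di]] <- n_ww[res_key[di]] + 1L
      n_ww[res_key[ai]] <- n_ww[res_key[ai]] + 1L
    } else if (cls == "W-SC" || cls == "SC-W") {
      wk <- res_key[if (dw) di else ai]
      n_sc[wk] <- n_sc[wk] + 1L
    }
  }
  typed <- n_any > 0
  tab <- table(n_sc[typed], n_ww[typed])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("n_sc", "n_ww", "n")
  df$n_sc <- as.integer(df$n_sc)
  df$n_ww <- as.integer(df$n_ww)
  df <- df[df$n > 0, ]
  df <- df[order(df$n_sc, df$n_ww), ]
  rownames(df) <- NULL
  structure(list(
    matrix = df,
    per_water = data.frame(water = wat_key, n_sc = as.integer(n_sc),
                           n_ww = as.integer(n_ww),
                           n_bonds = as.integer(n_any),
                           stringsAsFactors = FALSE),
    total_sc_w = sum(n_sc),
    total_w_w = sum(n_ww) / 2,
    isolated = sum(!typed),
    n_waters = length(wat_key)), class = "water_census")
}

#' @export
print.water_census <- function(x, ...) {
  cat(sprintf("water_census: %d waters, %d SC-W bonds, %g unique W-W bonds, %d without H-bonds\n",
              x$n_waters, x$total_sc_w, x$total_w_w, x$isolated))
  print(x$matrix)
  invisible(x)
}

#' Polymer residues without any hydrogen bond to water
#'
#' Lists, per chain, the residues that form no hydrogen bond (main-chain
#' or side-chain) to any water molecule. When a secondary-structure
#' assignment is supplied the helical subset is reported too.
#'
#' @param s an \code{ultra_structure}.
#' @param bonds output of \code{\link{find_hbonds}} on \code{s}.
#' @param ss optional result of \code{\link{assign_secondary_structure}}
#'   covering the structure's chains.
#' @return list with \code{by_chain} (character vectors of residue labels),
#'   \code{counts} per chain, and optionally \code{in_helix}.
#' @export
residues_without_water <- function(s, bonds, ss = NULL) {
  a <- s$atom
  res_key <- paste(a$chain, a$resno, a$insert, sep = "|")
  watered <- character(0)
  for (i in seq_len(nrow(bonds))) {
    di <- bonds$donor[i]
    ai <- bonds$acceptor[i]
    if (a$category[di] == "water" && a$category[ai] == "polymer")
      watered <- c(watered, res_key[ai])
    if (a$category[ai] == "water" && a$category[di] == "polymer")
      watered <- c(watered, res_key[di])
  }
  watered <- unique(watered)
  poly <- a$category == "polymer"
  res_tab <- unique(data.frame(key = res_key[poly], chain = a$chain[poly],
                               resno = a$resno[poly], resid = a$resid[poly],
                               stringsAsFactors = FALSE))
  dry <- res_tab[!res_tab$key %in% watered, ]
  by_chain <- split(sprintf("%s%s%d", dry$resid, dry$chain, dry$resno),
                    dry$chain)
  out <- list(by_chain = by_chain,
              counts = vapply(by_chain, length, integer(1)),
              dry = dry)
  if (!is.null(ss)) {
    helix_res <- character(0)
    for (el in ss) {
      if (grepl("helix", el$kind))
        helix_res <- c(helix_res, paste(el$chain, el$from:el$to, "", sep = "|"))
    }
    out$in_helix <- dry[dry$key %in% helix_res, ]
  }
  out
}

.N_TERM_DONORS <- c("N")
.SB_DONORS <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                   HIS = c("ND1", "NE2"))
.SB_ACCEPTORS <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))

#' Detect salt bridges
#'
#' Short contacts between protonated basic groups (Arg guanidinium, Lys
#' ammonium, His imidazolium, N-terminal amine) and carboxylate or
#' C-terminal oxygens. Records are at atom-contact level: when a donor
#' carries refined hydrogens, each hydrogen within \code{max_h} of an
#' acceptor oxygen yields its own record with the H...O distance (so two
#' guanidinium hydrogens reaching the same oxygen give two records);
#' donors without hydrogens are tested on the N...O distance against
#' \code{max_n}.
#'
#' @param s an \code{ultra_structure}.
#' @param max_h H...O cutoff (Angstrom) used when the donor hydrogen is
#'   present.
#' @param max_n N...O cutoff (Angstrom) used otherwise.
#' @return data.frame sorted by chain and residue: donor and acceptor
#'   labels, contact atoms, and \code{d_contact}.
#' @export
find_salt_bridges <- function(s, max_h = 3.2, max_n = 4.0) {
  a <- s$atom
  if (!nrow(a)) return(.empty_salt_bridges())
  name <- normalize_atom_name(a$elety)
  poly <- a$category == "polymer"
  parents <- .h_parents(a)
  h_of <- split(which(!is.na(parents)), parents[!is.na(parents)])

  don <- integer(0)
  for (i in which(poly)) {
    nm <- name[i]
    rs <- a$resid[i]
    if (!is.null(.SB_DONORS[[rs]]) && nm %in% .SB_DONORS[[rs]]) don <- c(don, i)
  }
  # N-terminal amine of each chain
  for (ch in unique(a$chain[poly])) {
    rows <- which(poly & a$chain == ch)
    first <- rows[a$resno[rows] == min(a$resno[rows])]
    don <- c(don, first[name[first] == "N"])
  }
  acc <- integer(0)
  for (i in which(poly)) {
    nm <- name[i]
    rs <- a$resid[i]
    if (!is.null(.SB_ACCEPTORS[[rs]]) && nm %in% .SB_ACCEPTORS[[rs]])
      acc <- c(acc, i)
  }
  for (ch in unique(a$chain[poly])) {
    rows <- which(poly & a$chain == ch)
    last <- rows[a$resno[rows] == max(a$resno[rows])]
    acc <- c(acc, last[name[last] %in% c("O", "OXT")])
  }
  acc <- unique(acc)
  don <- unique(don)
  if (!length(don) || !length(acc)) return(.empty_salt_bridges())

  res_key <- paste(a$chain, a$resno, a$insert, sep = "|")
  out <- list()
  for (di in don) {
    for (ai in acc) {
      if (res_key[di] == res_key[ai]) next
      if (!.altloc_compatible(a$alt[di], a$alt[ai])) next
      hyd <- h_of[[as.character(di)]]
      hyd <- hyd[.altloc_compatible(a$alt[hyd], a$alt[ai])]
      if (length(hyd)) {
        dh <- sqrt((a$x[hyd] - a$x[ai])^2 + (a$y[hyd] - a$y[ai])^2 +
                     (a$z[hyd] - a$z[ai])^2)
        for (q in which(dh <= max_h)) {
          out[[length(out) + 1]] <- data.frame(
            donor = di, hydrogen = hyd[q], acceptor = ai,
            donor_label = .atom_label(a, hyd[q]),
            acceptor_label = .atom_label(a, ai),
            d_contact = dh[q], via = "H", stringsAsFactors = FALSE)
        }
      } else {
        dno <- sqrt((a$x[di] - a$x[ai])^2 + (a$y[di] - a$y[ai])^2 +
                      (a$z[di] - a$z[ai])^2)
        if (dno <= max_n) {
          out[[length(out) + 1]] <- data.frame(
            donor = di, hydrogen = NA_integer_, acceptor = ai,
            donor_label = .atom_label(a, di),
            acceptor_label = .atom_label(a, ai),
            d_contact = dno, via = "N", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(.empty_salt_bridges())
  sb <- do.call(rbind, out)
  sb <- sb[order(a$chain[sb$donor], a$resno[sb$donor], sb$donor_label,
                 sb$acceptor_label), ]
  rownames(sb) <- NULL
  sb
}

.empty_salt_bridges <- function() {
  data.frame(donor = integer(0), hydrogen = integer(0), acceptor = integer(0),
             donor_label = character(0), acceptor_label = character(0),
             d_contact = numeric(0), via = character(0),
             stringsAsFactors = FALSE)
}

#' Calibrate hydrogen-bond criteria against target bond totals
#'
#' Sweeps the distance and angle cutoffs over a grid and reports, for each
#' setting, the side-chain-water and water-water bond totals together with
#' their relative error against the targets; both conventions for
#' main-chain-water bonds (excluded from, or merged into, the side-chain
#' total) are scored. The best-scoring setting is returned with the full
#' discrepancy report so the choice is auditable.
#'
#' @param s an \code{ultra_structure}.
#' @param target_sc,target_ww target side-chain-water and unique
#'   water-water bond counts.
#' @param max_da_grid,min_dha_grid grids to sweep.
#' @return list with \code{best} (an \code{hbond_criteria}),
#'   \code{mc_convention} (\code{"exclude"} or \code{"merge"}), and
#'   \code{report} (one row per setting).
#' @export
calibrate_hbond_criteria <- function(s, target_sc = 285, target_ww = 139,
                                     max_da_grid = seq(2.9, 3.6, by = 0.1),
                                     min_dha_grid = c(90, 120)) {
  rows <- list()
  for (da in max_da_grid) {
    for (ang in min_dha_grid) {
      cr <- hbond_criteria(max_da = da, min_dha = ang,
                           max_ha = max(2.5, da - 0.9))
      bonds <- suppressWarnings(find_hbonds(s, cr))
      cen <- water_census(bonds, s)
      n_mcw <- sum(bonds$class %in% c("MC-W", "W-MC"))
      for (conv in c("exclude", "merge")) {
        sc <- cen$total_sc_w + if (conv == "merge") n_mcw else 0
        err <- abs(sc - target_sc) / target_sc +
          abs(cen$total_w_w - target_ww) / target_ww
        rows[[length(rows) + 1]] <- data.frame(
          max_da = da, min_dha = ang, mc_convention = conv,
          sc_w = sc, w_w = cen$total_w_w, score = err,
          stringsAsFactors = FALSE)
      }
    }
  }
  report <- do.call(rbind, rows)
  best <- report[which.min(report$score), ]
  list(best = hbond_criteria(max_da = best$max_da, min_dha = best$min_dha,
                             max_ha = max(2.5, best$max_da - 0.9)),
       mc_convention = best$mc_convention,
       report = report)
}
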