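# Rule-based secondary-structure assignment from backbone torsions and
# main-chain hydrogen-bond patterns: alpha/3-10/pi helices, strands,
# antiparallel sheets, type I turns, open alpha-turns and capping bonds.

#' Ramachandran-region configuration for the assigner
#'
#' The region boundaries are declared configuration, not fitted values:
#' helical phi/psi in [-100, -30] x [-80, -5]; beta-strand phi in
#' [-180, -45] with psi in [90, 180] or [-180, -170]. Type-I-turn
#' canonical torsions are (-60, -30) at i+1 and (-90, 0) at i+2, matched
#' within \code{turn_tol}.
#'
#' @param helix_phi,helix_psi,beta_phi,beta_psi_1,beta_psi_2 numeric
#'   length-2 ranges in degrees.
#' @param turn_tol tolerance (degrees) for type-I-turn torsions.
#' @return list of class \code{ss_regions}.
#' @export
ss_regions <- function(helix_phi = c(-100, -30), helix_psi = c(-80, -5),
                       beta_phi = c(-180, -45), beta_psi_1 = c(90, 180),
                       beta_psi_2 = c(-180, -170), turn_tol = 30) {
  structure(list(helix_phi = helix_phi, helix_psi = helix_psi,
                 beta_phi = beta_phi, beta_psi_1 = beta_psi_1,
                 beta_psi_2 = beta_psi_2, turn_tol = turn_tol),
            class = "ss_regions")
}

.in_range <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]

# main conformer rows of a polymer chain, as a per-residue list of row sets
.chain_residues <- function(a, ch) {
  rows <- which(a$chain == ch & a$category == "polymer")
  if (!length(rows)) return(list())
  key <- paste(a$resno[rows], a$insert[rows], sep = "|")
  grp <- split(rows, factor(key, levels = unique(key)))
  grp[order(vapply(grp, function(g) a$resno[g[1]], numeric(1)))]
}

.pick_atom <- function(a, rows, nm) {
  cand <- rows[normalize_atom_name(a$elety[rows]) == nm]
  if (!length(cand)) return(NA_integer_)
  blank <- cand[a$alt[cand] == ""]
  if (length(blank)) return(blank[1])
  cand[order(a$alt[cand])][1]
}

#' Backbone phi/psi/omega torsions of a chain
#'
#' phi is C(i-1)-N-CA-C, psi is N-CA-C-N(i+1) and omega is
#' CA(i-1)-C(i-1)-N-CA, undefined (NA) where the flanking residue is
#' absent. Where a residue is split into conformers the blank-altloc or
#' first-label backbone is used.
#'
#' @param s an \code{ultra_structure}.
#' @param chain chain identifier.
#' @return data.frame with resno, resid, phi, psi, omega (degrees).
#' @export
backbone_torsions <- function(s, chain) {
  a <- s$atom
  res <- .chain_residues(a, chain)
  n <- length(res)
  out <- data.frame(resno = vapply(res, function(g) a$resno[g[1]], numeric(1)),
                    resid = vapply(res, function(g) a$resid[g[1]], character(1)),
                    phi = NA_real_, psi = NA_real_, omega = NA_real_)
  if (!n) return(out)
  N <- vapply(res, function(g) .pick_atom(a, g, "N"), integer(1))
  CA <- vapply(res, function(g) .pick_atom(a, g, "CA"), integer(1))
  C <- vapply(res, function(g) .pick_atom(a, g, "C"), integer(1))
  co <- function(i) c(a$x[i], a$y[i], a$z[i])
  for (i in seq_len(n)) {
    if (i > 1 && !anyNA(c(C[i - 1], N[i], CA[i], C[i]))) {
      out$phi[i] <- dihedral_angle(co(C[i - 1]), co(N[i]), co(CA[i]), co(C[i]))
      if (!anyNA(c(CA[i - 1], C[i - 1], N[i], CA[i])))
        out$omega[i] <- dihedral_angle(co(CA[i - 1]), co(C[i - 1]), co(N[i]),
                                       co(CA[i]))
    }
    if (i < n && !anyNA(c(N[i], CA[i], C[i], N[i + 1])))
      out$psi[i] <- dihedral_angle(co(N[i]), co(CA[i]), co(C[i]),
                                   co(N[i + 1]))
  }
  out
}

#' Classify main-chain CO...HN hydrogen bonds by residue offset
#'
#' Filters a bond list down to backbone carbonyl-to-amide bonds and
#' classifies each as helical (donor residue minus acceptor residue
#' offset k in 3, 4, 5, within one chain) or cross-strand (larger offsets
#' or different chains). Bifurcated acceptors are retained.
#'
#' @param s an \code{ultra_structure}.
#' @param bonds output of \code{\link{find_hbonds}}.
#' @return list with \code{helical} (chain, i = acceptor resno, k) and
#'   \code{cross} (acceptor chain/resno, donor chain/resno) data.frames.
#' @export
mainchain_hbond_pattern <- function(s, bonds) {
  a <- s$atom
  nm <- normalize_atom_name(a$elety)
  is_bbN <- a$category == "polymer" & nm == "N"
  is_bbO <- a$category == "polymer" & nm == "O"
  keep <- is_bbN[bonds$donor] & is_bbO[bonds$acceptor]
  mb <- bonds[keep, , drop = FALSE]
  hel <- list(); crs <- list()
  for (i in seq_len(nrow(mb))) {
    di <- mb$donor[i]; ai <- mb$acceptor[i]
    if (a$chain[di] == a$chain[ai]) {
      k <- a$resno[di] - a$resno[ai]
      if (k %in% 3:5) {
        hel[[length(hel) + 1]] <- data.frame(
          chain = a$chain[ai], i = a$resno[ai], k = k,
          stringsAsFactors = FALSE)
        next
      }
      if (abs(k) <= 2) next
    }
    crs[[length(crs) + 1]] <- data.frame(
      chain_acc = a$chain[ai], resno_acc = a$resno[ai],
      chain_don = a$chain[di], resno_don = a$resno[di],
      stringsAsFactors = FALSE)
  }
  list(helical = if (length(hel)) do.call(rbind, hel) else
    data.frame(chain = character(0), i = numeric(0), k = numeric(0)),
    cross = if (length(crs)) do.call(rbind, crs) else
      data.frame(chain_acc = character(0), resno_acc = numeric(0),
                 chain_don = character(0), resno_don = numeric(0)))
}

.new_element <- function(kind, chain, from, to, ...) {
  c(list(kind = kind, chain = chain, from = from, to = to), list(...))
}

#' Assign secondary-structure elements
#'
#' Applies, in order: (1) residues with helical phi/psi or covered by a
#' helical i->i+k main-chain bond (k = 3, 4, 5) are merged into maximal
#' helix runs; a run is a helix when it has at least two supporting bonds,
#' or one bond with uniformly helical torsions over at least four
#' residues; its kind follows the dominant offset (4 alpha, 3 three-ten),
#' with all offsets retained as sub-annotations (a single i->i+5 inside an
#' alpha run marks one turn of pi-helix). (2) Maximal beta-region runs of
#' length >= 2 outside helices become strands, recording both the phi/psi
#' extent and the (possibly shorter) cross-strand hydrogen-bond extent.
#' (3) Strand pairs joined by cross-strand main-chain bonds form
#' antiparallel sheets. (4) A lone i->i+3 bond whose two central residues
#' match canonical type-I torsions within tolerance is a type I turn.
#' (5) A lone i->i+4 bond outside any helix is an open alpha-turn.
#' (6) Side-chain-to-main-chain bonds at helix termini are recorded as
#' caps.
#'
#' @param s an \code{ultra_structure}.
#' @param bonds optional precomputed \code{\link{find_hbonds}} result.
#' @param criteria \code{\link{hbond_criteria}} used when \code{bonds} is
#'   not supplied.
#' @param regions an \code{\link{ss_regions}} configuration.
#' @return object of class \code{ss_assignment}: list of elements, with
#'   the per-residue torsion/region table in \code{attr(, "residues")}.
#' @export
assign_secondary_structure <- function(s, bonds = NULL,
                                       criteria = hbond_criteria(),
                                       regions = ss_regions()) {
  a <- s$atom
  if (is.null(bonds)) bonds <- suppressWarnings(find_hbonds(s, criteria))
  pat <- mainchain_hbond_pattern(s, bonds)
  chains <- unique(a$chain[a$category == "polymer"])
  elements <- list()
  res_tables <- list()
  for (ch in chains) {
    tor <- backbone_torsions(s, ch)
    n <- nrow(tor)
    if (!n) next
    helical_pp <- .in_range(tor$phi, regions$helix_phi) &
      .in_range(tor$psi, regions$helix_psi)
    beta_pp <- .in_range(tor$phi, regions$beta_phi) &
      (.in_range(tor$psi, regions$beta_psi_1) |
         .in_range(tor$psi, regions$beta_psi_2))
    hb <- pat$helical[pat$helical$chain == ch, , drop = FALSE]
    covered <- rep(FALSE, n)
    idx_of <- function(rn) match(rn, tor$resno)
    for (r in seq_len(nrow(hb))) {
      i0 <- idx_of(hb$i[r])
      if (is.na(i0)) next
      covered[i0:min(n, i0 + hb$k[r])] <- TRUE
    }
    # torsions decide membership; a chain-terminal residue with one
    # undefined torsion joins when spanned by a helical bond, provided
    # its defined torsion is itself helical
    partial_hel <- (is.na(tor$phi) | is.na(tor$psi)) &
      (is.na(tor$phi) | .in_range(tor$phi, regions$helix_phi)) &
      (is.na(tor$psi) | .in_range(tor$psi, regions$helix_psi))
    in_helix <- helical_pp | (covered & partial_hel)
    runs <- .runs(in_helix)
    helix_mask <- rep(FALSE, n)
    helix_bounds <- rep(FALSE, n)
    for (r in seq_len(nrow(runs))) {
      lo <- runs$from[r]; hi <- runs$to[r]
      rb <- hb[idx_of(hb$i) >= lo & idx_of(hb$i) + hb$k <= hi, , drop = FALSE]
      all_helical <- all(helical_pp[lo:hi] | is.na(tor$phi[lo:hi]))
      is_helix <- nrow(rb) >= 2 ||
        (nrow(rb) >= 1 && all_helical && hi - lo + 1 >= 4)
      if (!is_helix) next
      helix_mask[lo:hi] <- TRUE
      helix_bounds[c(lo, hi)] <- TRUE
      offs <- table(rb$k)
      dom <- as.integer(names(offs)[which.max(offs)])
      kind <- unname(c(`3` = "three_ten_helix", `4` = "alpha_helix",
                       `5` = "pi_turn")[as.character(dom)])
      caps <- .helix_caps(a, bonds, ch, tor$resno[lo], tor$resno[hi])
      elements[[length(elements) + 1]] <- .new_element(
        kind, ch, tor$resno[lo], tor$resno[hi],
        offsets = as.integer(rep(as.integer(names(offs)), offs)),
        n_bonds = nrow(rb), caps = caps,
        sub_annotation = if (length(offs) > 1)
          sprintf("mixed helical bonds (offsets %s)",
                  paste(names(offs), collapse = ",")) else NULL)
    }
    # strands from phi/psi outside helices
    strand_mask <- beta_pp & !helix_mask
    sruns <- .runs(strand_mask)
    sruns <- sruns[sruns$to - sruns$from + 1 >= 2, , drop = FALSE]
    cross <- pat$cross
    for (r in seq_len(nrow(sruns))) {
      lo <- sruns$from[r]; hi <- sruns$to[r]
      rn <- tor$resno[lo:hi]
      involved <- c(cross$resno_acc[cross$chain_acc == ch &
                                      cross$resno_acc %in% rn],
                    cross$resno_don[cross$chain_don == ch &
                                      cross$resno_don %in% rn])
      elements[[length(elements) + 1]] <- .new_element(
        "strand", ch, tor$resno[lo], tor$resno[hi],
        phipsi_extent = c(tor$resno[lo], tor$resno[hi]),
        hbond_extent = if (length(involved))
          range(involved) else c(NA_real_, NA_real_))
    }
    # type I turns and open alpha-turns outside helices
    # a turn record needs both bond endpoints outside a helix or exactly
    # at a helix boundary (the open alpha-turn continuing past a helix
    # terminus); bonds reaching into a helix interior are helical capping
    free_end <- function(ix) !helix_mask[ix] || helix_bounds[ix]
    for (r in seq_len(nrow(hb))) {
      i0 <- idx_of(hb$i[r])
      if (is.na(i0)) next
      hi <- i0 + hb$k[r]
      if (hi > n) next
      if (all(helix_mask[i0:hi])) next
      if (!free_end(i0) || !free_end(hi)) next
      if (hb$k[r] == 3) {
        ok1 <- !is.na(tor$phi[i0 + 1]) &&
          abs(tor$phi[i0 + 1] - (-60)) <= regions$turn_tol &&
          abs(tor$psi[i0 + 1] - (-30)) <= regions$turn_tol
        ok2 <- !is.na(tor$phi[i0 + 2]) &&
          abs(tor$phi[i0 + 2] - (-90)) <= regions$turn_tol &&
          abs(tor$psi[i0 + 2] - 0) <= regions$turn_tol
        if (ok1 && ok2)
          elements[[length(elements) + 1]] <- .new_element(
            "turn_I", ch, tor$resno[i0], tor$resno[hi])
      }
      if (hb$k[r] == 4)
        elements[[length(elements) + 1]] <- .new_element(
          "open_alpha_turn", ch, tor$resno[i0], tor$resno[hi])
    }
    tor$region <- ifelse(helical_pp, "helical", ifelse(beta_pp, "beta", "other"))
    tor$chain <- ch
    res_tables[[ch]] <- tor
  }
  # sheets: pair strands sharing cross-strand bonds
  strands <- which(vapply(elements, function(e) e$kind == "strand", logical(1)))
  cross <- pat$cross
  if (length(strands) >= 2 && nrow(cross)) {
    for (p in seq_along(strands)) {
      for (q in seq_along(strands)) {
        if (q <= p) next
        e1 <- elements[[strands[p]]]; e2 <- elements[[strands[q]]]
        hit <- (cross$chain_acc == e1$chain &
                  cross$resno_acc >= e1$from & cross$resno_acc <= e1$to &
                  cross$chain_don == e2$chain &
                  cross$resno_don >= e2$from & cross$resno_don <= e2$to) |
          (cross$chain_acc == e2$chain &
             cross$resno_acc >= e2$from & cross$resno_acc <= e2$to &
             cross$chain_don == e1$chain &
             cross$resno_don >= e1$from & cross$resno_don <= e1$to)
        if (any(hit))
          elements[[length(elements) + 1]] <- .new_element(
            "sheet", paste(e1$chain, e2$chain, sep = "/"),
            NA, NA, pair = list(
              list(chain = e1$chain, from = e1$from, to = e1$to),
              list(chain = e2$chain, from = e2$from, to = e2$to)),
            n_bonds = sum(hit), topology = "antiparallel")
      }
    }
  }
  structure(elements, class = "ss_assignment",
            residues = do.call(rbind, res_tables))
}

.runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(from = starts[r$values], to = ends[r$values])
}

.helix_caps <- function(a, bonds, ch, rn_from, rn_to) {
  if (!nrow(bonds)) return(character(0))
  nm <- normalize_atom_name(a$elety)
  grp <- .atom_groups(a)
  out <- character(0)
  for (i in seq_len(nrow(bonds))) {
    di <- bonds$donor[i]; ai <- bonds$acceptor[i]
    pair <- c(di, ai)
    sc <- pair[grp[pair] == "SC"]
    mc <- pair[grp[pair] == "MC" & nm[pair] %in% c("N", "O")]
    if (length(sc) != 1 || length(mc) != 1) next
    if (a$chain[mc] != ch) next
    near_end <- a$resno[mc] <= rn_from + 1 || a$resno[mc] >= rn_to - 1
    if (a$resno[mc] >= rn_from - 1 && a$resno[mc] <= rn_to + 1 && near_end)
      out <- c(out, sprintf("%s -> %s", .atom_label(a, sc),
                            .atom_label(a, mc)))
  }
  unique(out)
}

#' @export
print.ss_assignment <- function(x, ...) {
  cat(sprintf("ss_assignment: %d elements\n", length(x)))
  for (e in x) {
    if (e$kind == "sheet") {
      p <- e$pair
      cat(sprintf("  sheet (%s): %s %d-%d | %s %d-%d (%d bonds)\n",
                  e$topology, p[[1]]$chain, p[[1]]$from, p[[1]]$to,
                  p[[2]]$chain, p[[2]]$from, p[[2]]$to, e$n_bonds))
    } else {
      cat(sprintf("  %s %s %d-%d%s\n", e$kind, e$chain, e$from, e$to,
                  if (!is.null(e$sub_annotation))
                    paste0(" [", e$sub_annotation, "]") else ""))
    }
  }
  invisible(x)
}
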