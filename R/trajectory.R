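# Multi-model trajectory analysis: torsion time series, running RMSD
# kinetics (coordinate and circular torsion variants) and per-molecule
# endpoint RMSD.

# resolve "chain:resno:atom" or a list(chain, resno, elety, alt) to a row
.resolve_atom <- function(s, spec) {
  a <- s$atom
  if (is.character(spec)) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop(sprintf("bad atom spec '%s'", spec))
    spec <- list(chain = parts[1], resno = as.integer(parts[2]),
                 elety = parts[3], alt = if (length(parts) > 3) parts[4] else NULL)
  }
  rows <- which(a$chain == spec$chain & a$resno == spec$resno &
                  normalize_atom_name(a$elety) ==
                    normalize_atom_name(spec$elety))
  if (!is.null(spec$alt) && nzchar(spec$alt))
    rows <- rows[a$alt[rows] == spec$alt]
  if (!length(rows))
    stop(sprintf("atom %s:%s:%s not found", spec$chain, spec$resno, spec$elety))
  blank <- rows[a$alt[rows] == ""]
  if (length(blank)) blank[1] else rows[order(a$alt[rows])][1]
}

#' Torsion time series over a trajectory
#'
#' The named four-atom dihedral evaluated in every model of a multi-model
#' structure. Optionally unwrapped: successive values are shifted by
#' multiples of 360 degrees so the series is continuous (useful when a
#' torsion diffuses across the +/-180 seam).
#'
#' @param traj an \code{ultra_structure} with one or more models.
#' @param quad list or character vector of four atom specifiers
#'   (\code{"chain:resno:atom"}).
#' @param unwrap logical; return an additionally unwrapped series.
#' @return object of class \code{torsion_series}: data.frame with
#'   \code{frame}, \code{angle} (wrapped, degrees in (-180, 180]) and
#'   optionally \code{unwrapped}.
#' @export
torsion_series <- function(traj, quad, unwrap = FALSE) {
  idx <- vapply(quad, function(q) .resolve_atom(traj, q), integer(1))
  nm <- n_models(traj)
  ang <- numeric(nm)
  for (f in seq_len(nm)) {
    co <- atom_coords(traj, idx, model = f)
    ang[f] <- dihedral_angle(co[1, ], co[2, ], co[3, ], co[4, ])
  }
  out <- data.frame(frame = seq_len(nm), angle = ang)
  if (unwrap) {
    u <- ang
    for (f in seq_len(nm)[-1])
      u[f] <- u[f - 1] + circ_diff(ang[f], ang[f - 1])
    out$unwrapped <- u
  }
  structure(out, class = c("torsion_series", "data.frame"),
            quad = vapply(quad, function(q)
              if (is.character(q)) q else
                paste(q$chain, q$resno, q$elety, sep = ":"), character(1)))
}

#' Per-model RMSD against a reference frame
#'
#' Coordinate RMSD of each model against a reference model, optionally
#' after Kabsch superposition of the selection.
#'
#' @param traj a multi-model \code{ultra_structure}.
#' @param reference reference model index (default 1).
#' @param selection integer atom-row indices (default: all CA atoms, or
#'   all atoms when no CA present).
#' @param superpose superpose each frame on the reference first.
#' @return data.frame with \code{frame} and \code{rmsd} (Angstrom).
#' @export
rmsd_kinetics <- function(traj, reference = 1, selection = NULL,
                          superpose = TRUE) {
  a <- traj$atom
  if (is.null(selection)) {
    selection <- which(normalize_atom_name(a$elety) == "CA" &
                         a$category == "polymer")
    if (!length(selection)) selection <- seq_len(nrow(a))
  }
  ref <- atom_coords(traj, selection, model = reference)
  nm <- n_models(traj)
  rmsd <- vapply(seq_len(nm), function(f) {
    cur <- atom_coords(traj, selection, model = f)
    if (superpose) kabsch_superpose(cur, ref)$rmsd
    else sqrt(mean(rowSums((cur - ref)^2)))
  }, numeric(1))
  data.frame(frame = seq_len(nm), rmsd = rmsd)
}

#' Sliding-window circular RMSD of a torsion series
#'
#' The root-mean-square circular deviation of a torsion from its circular
#' mean, in a sliding window along the trajectory — an operationalisation
#' of "torsion-angle RMSD kinetics". Angular differences are taken on the
#' circle, so a series hovering around the +/-180 seam is handled
#' correctly and a window of constant torsion gives exactly zero.
#'
#' @param series a \code{\link{torsion_series}} (or numeric vector of
#'   angles in degrees).
#' @param window window width in frames (default 10).
#' @return data.frame with the window-end \code{frame} and
#'   \code{torsion_rmsd} (degrees).
#' @export
torsion_rmsd_kinetics <- function(series, window = 10) {
  ang <- if (is.data.frame(series)) series$angle else as.numeric(series)
  n <- length(ang)
  if (window < 2 || window > n)
    stop("window must be between 2 and the number of frames")
  out <- data.frame(frame = window:n, torsion_rmsd = NA_real_)
  for (e in window:n) {
    w <- ang[(e - window + 1):e]
    rad <- w / DEG
    mean_ang <- atan2(mean(sin(rad)), mean(cos(rad))) * DEG
    dev <- circ_diff(w, mean_ang)
    out$torsion_rmsd[e - window + 1] <- sqrt(mean(dev^2))
  }
  out
}

#' Final-frame RMSD per molecule grouping
#'
#' RMSD of the last model against the first, computed per chain group
#' (e.g. molecule 1 = chains A and B, molecule 2 = chains C and D),
#' superposed on CA atoms by default.
#'
#' @param traj a multi-model \code{ultra_structure}.
#' @param groupings named list of chain-identifier vectors.
#' @param atoms \code{"CA"} (default) or \code{"all"} heavy atoms.
#' @return data.frame with \code{group} and \code{rmsd} (Angstrom).
#' @export
endpoint_rmsd <- function(traj, groupings, atoms = c("CA", "all")) {
  atoms <- match.arg(atoms)
  a <- traj$atom
  last <- n_models(traj)
  res <- lapply(names(groupings), function(g) {
    chains <- groupings[[g]]
    if (!all(chains %in% a$chain)) stop(sprintf("unknown chain in group %s", g))
    sel <- which(a$chain %in% chains & a$category == "polymer" &
                   (if (atoms == "CA") normalize_atom_name(a$elety) == "CA"
                    else a$elesy != "H"))
    start <- atom_coords(traj, sel, model = 1)
    end <- atom_coords(traj, sel, model = last)
    data.frame(group = g,
               rmsd = if (last == 1) 0 else kabsch_superpose(end, start)$rmsd,
               n_atoms = length(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
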