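# Altloc- and occupancy-aware structure model and PDB/mmCIF input-output.
# Record parsing is delegated to bio3d; the unit cell line and the
# validation the analyses depend on (occupancy sums, altloc uniqueness)
# are handled here.

.category_of <- function(resid, type) {
  ifelse(resid %in% .WATER_RES, "water",
    ifelse(resid %in% .METAL_RES, "metal",
      ifelse(resid %in% .AA3 & type == "ATOM", "polymer",
        ifelse(resid %in% .AA3, "polymer", "ligand"))))
}

#' Construct a structure object from an atom table
#'
#' The in-memory model used by every analysis stage: a flat atom table
#' (one row per atom record, so alternate conformers occupy separate rows)
#' plus optional crystal information and optional extra coordinate models
#' for trajectories.
#'
#' @param atom data.frame with columns \code{elety} (atom name),
#'   \code{resid} (3-letter residue name), \code{chain}, \code{resno};
#'   optional \code{insert}, \code{alt}, \code{o}, \code{b}, \code{elesy},
#'   \code{type}, and coordinates \code{x}, \code{y}, \code{z}.
#' @param crystal optional list with \code{a}, \code{b}, \code{c} (Angstrom),
#'   \code{alpha}, \code{beta}, \code{gamma} (degrees), \code{space_group}.
#' @param xyz optional coordinate matrix (models x 3N) for multi-model
#'   structures; row 1 must equal the atom-table coordinates.
#' @param title optional character title.
#' @return an object of class \code{ultra_structure}.
#' @export
new_structure <- function(atom, crystal = NULL, xyz = NULL, title = "") {
  stopifnot(is.data.frame(atom))
  n <- nrow(atom)
  atom$type <- atom$type %||% rep("ATOM", n)
  atom$insert <- as.character(atom$insert %||% rep("", n))
  atom$alt <- as.character(atom$alt %||% rep("", n))
  atom$o <- atom$o %||% rep(1, n)
  atom$b <- atom$b %||% rep(0, n)
  atom$eleno <- atom$eleno %||% seq_len(n)
  atom$insert[is.na(atom$insert)] <- ""
  atom$alt[is.na(atom$alt)] <- ""
  atom$o[is.na(atom$o)] <- 1
  atom$b[is.na(atom$b)] <- 0
  if (is.null(atom$elesy) || anyNA(atom$elesy)) {
    guess <- .element_from_name(atom$elety)
    if (is.null(atom$elesy)) atom$elesy <- guess
    atom$elesy[is.na(atom$elesy)] <- guess[is.na(atom$elesy)]
  }
  atom$type[!atom$resid %in% .AA3] <- "HETATM"
  atom$category <- .category_of(atom$resid, atom$type)
  if (n && (any(atom$o < 0) || any(atom$o > 1 + 1e-6)))
    stop("occupancies must lie in [0, 1]")
  if (n && any(atom$b < 0)) stop("B-factors must be non-negative")
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, atom$alt)
  if (anyDuplicated(key))
    stop("duplicate atom: same residue, name and altloc appears twice")
  if (is.null(xyz)) {
    xyz <- matrix(as.numeric(t(as.matrix(atom[, c("x", "y", "z")]))), nrow = 1)
  }
  s <- structure(list(atom = atom, xyz = xyz, crystal = crystal,
                      title = title),
                 class = "ultra_structure")
  .check_altloc_occupancy(s)
  s
}

.element_from_name <- function(elety) {
  stripped <- gsub("[0-9']", "", elety)
  two <- toupper(substr(stripped, 1, 2))
  one <- toupper(substr(stripped, 1, 1))
  ifelse(two %in% c("ZN", "MG", "NA", "FE", "CU", "MN", "CL", "BR", "SE",
                    "CD", "NI", "CO", "HG"),
         two, one)
}

.check_altloc_occupancy <- function(s) {
  a <- s$atom
  split_key <- paste(a$chain, a$resno, a$insert, a$elety)
  has_alt <- a$alt != ""
  if (!any(has_alt)) return(invisible(TRUE))
  sums <- tapply(a$o[has_alt], split_key[has_alt], sum)
  bad <- sums > 1 + 1e-6
  if (any(bad))
    warning(sprintf("altloc occupancies exceed 1 for: %s",
                    paste(names(sums)[bad], collapse = "; ")))
  invisible(TRUE)
}

.parse_cryst1 <- function(line) {
  list(a = as.numeric(substr(line, 7, 15)),
       b = as.numeric(substr(line, 16, 24)),
       c = as.numeric(substr(line, 25, 33)),
       alpha = as.numeric(substr(line, 34, 40)),
       beta = as.numeric(substr(line, 41, 47)),
       gamma = as.numeric(substr(line, 48, 54)),
       space_group = trimws(substr(line, 56, 66)))
}

.validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (anyNA(coords))
      stop(sprintf("malformed coordinate record at line %d: %s", i,
                   trimws(ln)))
  }
  invisible(TRUE)
}

#' Read a macromolecular coordinate file
#'
#' Reads PDB (fixed-column v3) or mmCIF into the package's structure
#' model. All ATOM/HETATM records are kept, including hydrogens and every
#' alternate conformer; waters, metals and small-molecule solvates are
#' categorised from their residue names; the CRYST1 cell and space group
#' are retained when present. Multi-MODEL files become trajectory
#' structures with one coordinate row per model.
#'
#' @param source a file path, or the file content as a single string.
#' @param format \code{"pdb"} (default) or \code{"mmcif"}.
#' @return an \code{ultra_structure}.
#' @export
read_structure <- function(source, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  is_path <- length(source) == 1L && !grepl("\n", source) &&
    file.exists(source)
  path <- if (is_path) {
    source
  } else {
    tf <- tempfile(fileext = paste0(".", ifelse(format == "pdb", "pdb", "cif")))
    writeLines(if (length(source) > 1) source else
      strsplit(source, "\n", fixed = TRUE)[[1]], tf)
    tf
  }
  crystal <- NULL
  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    .validate_pdb_lines(lines)
    cl <- grep("^CRYST1", lines, value = TRUE)
    if (length(cl)) crystal <- .parse_cryst1(cl[1])
    if (!any(substr(lines, 1, 6) %in% c("ATOM  ", "HETATM"))) {
      return(new_structure(.empty_atom_table(), crystal = crystal))
    }
    pdb <- suppressWarnings(
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, rm.insert = FALSE,
                      verbose = FALSE))
  } else {
    pdb <- suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  }
  at <- pdb$atom
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  if (anyNA(at$elesy) || all(at$elesy == "")) {
    missing <- is.na(at$elesy) | at$elesy == ""
    if (any(missing)) {
      warning("element symbols missing; inferred from atom names")
      at$elesy[missing] <- .element_from_name(at$elety[missing])
    }
  }
  atom <- data.frame(type = at$type, eleno = at$eleno, elety = at$elety,
                     alt = at$alt, resid = at$resid, chain = at$chain,
                     resno = at$resno, insert = at$insert,
                     x = at$x, y = at$y, z = at$z,
                     o = ifelse(is.na(at$o), 1, at$o),
                     b = ifelse(is.na(at$b), 0, at$b),
                     elesy = at$elesy,
                     stringsAsFactors = FALSE)
  xyz <- unclass(pdb$xyz)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  new_structure(atom, crystal = crystal, xyz = xyz,
                title = if (is_path) basename(source) else "")
}

.empty_atom_table <- function() {
  data.frame(type = character(0), eleno = integer(0), elety = character(0),
             alt = character(0), resid = character(0), chain = character(0),
             resno = integer(0), insert = character(0), x = numeric(0),
             y = numeric(0), z = numeric(0), o = numeric(0), b = numeric(0),
             elesy = character(0), stringsAsFactors = FALSE)
}

.cryst1_line <- function(cr) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
          cr$a, cr$b, cr$c, cr$alpha, cr$beta, cr$gamma, cr$space_group)
}

#' Write a structure as PDB-format text
#'
#' Fixed-column v3 output. Re-reading the text reproduces the structure up
#' to format rounding (coordinates 1e-3 Angstrom, occupancy 1e-2).
#'
#' @param s an \code{ultra_structure}.
#' @param file optional path; when given the text is also written there.
#' @return the PDB text, invisibly when \code{file} is given.
#' @export
write_structure <- function(s, file = NULL) {
  stopifnot(inherits(s, "ultra_structure"))
  a <- s$atom
  if (nrow(a) && any(nchar(a$chain) > 1))
    stop("PDB format allows single-character chain identifiers only")
  header <- character(0)
  if (!is.null(s$crystal)) header <- .cryst1_line(s$crystal)
  if (nrow(a) == 0) {
    txt <- paste(c(header, "END"), collapse = "\n")
  } else {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf), add = TRUE)
    suppressWarnings(bio3d::write.pdb(
      pdb = NULL, file = tf, xyz = s$xyz, type = a$type, resno = a$resno,
      resid = a$resid, eleno = a$eleno, elety = a$elety, chain = a$chain,
      insert = ifelse(a$insert == "", NA, a$insert),
      alt = ifelse(a$alt == "", NA, a$alt), o = a$o, b = a$b,
      elesy = a$elesy))
    body <- readLines(tf, warn = FALSE)
    txt <- paste(c(header, body), collapse = "\n")
  }
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Expand a residue into its single-conformer components
#'
#' Atoms with a blank altloc are shared by every conformer; atoms carrying
#' a conformer label go only to that conformer. The weight of a conformer
#' is the occupancy of its labelled atoms. A fully ordered residue yields
#' one conformer of weight 1.
#'
#' @param r a residue: the rows of a structure atom table belonging to one
#'   (chain, resno, insert) group.
#' @return list of \code{list(residue = <atom table>, altloc = <label>,
#'   weight = <occupancy>)}.
#' @export
conformer_expand <- function(r) {
  stopifnot(is.data.frame(r), nrow(r) > 0)
  if (anyDuplicated(paste(r$elety, r$alt)))
    stop("conflicting duplicate atoms with the same altloc label")
  labs <- sort(setdiff(unique(r$alt), ""))
  if (!length(labs))
    return(list(list(residue = r, altloc = "", weight = 1)))
  lapply(labs, function(lb) {
    sub <- r[r$alt %in% c("", lb), , drop = FALSE]
    list(residue = sub, altloc = lb,
         weight = mean(r$o[r$alt == lb]))
  })
}

# ---- accessors ------------------------------------------------------------

#' Number of water molecules in a structure
#' @param s an \code{ultra_structure}.
#' @return integer count of water residues.
#' @export
water_count <- function(s) {
  a <- s$atom[s$atom$category == "water", ]
  length(unique(paste(a$chain, a$resno, a$insert)))
}

#' Number of coordinate models
#' @param s an \code{ultra_structure}.
#' @return integer; more than 1 indicates a trajectory.
#' @export
n_models <- function(s) nrow(s$xyz)

# Coordinates of selected atom rows for a given model, as an n x 3 matrix.
atom_coords <- function(s, idx = seq_len(nrow(s$atom)), model = 1) {
  v <- s$xyz[model, ]
  cbind(x = v[3 * (idx - 1) + 1], y = v[3 * (idx - 1) + 2],
        z = v[3 * (idx - 1) + 3])
}

# Split the atom table into residues, in file order.
residue_groups <- function(a) {
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  split(seq_len(nrow(a)), factor(key, levels = unique(key)))
}

#' @export
print.ultra_structure <- function(x, ...) {
  a <- x$atom
  nres <- length(residue_groups(a))
  cat(sprintf("ultra_structure: %d atoms, %d residues, %d chain(s), %d model(s)\n",
              nrow(a), nres, length(unique(a$chain[!is.na(a$chain)])),
              n_models(x)))
  tab <- table(a$category)
  if (length(tab))
    cat("  categories:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
  if (!is.null(x$crystal))
    cat(sprintf("  cell: a=%.3f b=%.3f c=%.3f  %s\n", x$crystal$a,
                x$crystal$b, x$crystal$c, x$crystal$space_group))
  invisible(x)
}
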