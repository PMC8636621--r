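# Residue-centric structure model and readers built on bio3d.
#
# A Structure keeps the flat atom table (author chain/residue numbering
# preserved verbatim) plus a derived residue table; all downstream modules
# address residues through their row index in that table.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL", "HSD", "HSE", "HSP", "HID",
          "HIE", "HIP", "CYX", "ASH", "GLH", "LYN")
.NUC <- c("DA", "DC", "DG", "DT", "DI", "DU", "A", "C", "G", "U", "I", "T",
          "ADE", "CYT", "GUA", "THY", "URA", "RA", "RC", "RG", "RU")

polymer_class <- function(resname) {
  resname <- toupper(trimws(resname))
  out <- rep("other", length(resname))
  out[resname %in% .AA3] <- "protein"
  out[resname %in% .NUC] <- "nucleic"
  out
}

guess_element <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    bad <- is.na(e) | e == ""
    if (!any(bad)) return(e)
  } else {
    e <- rep("", length(elety))
    bad <- rep(TRUE, length(elety))
  }
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", trimws(elety[bad]))))
  # polymer atom names: first letter is the element (CA is C-alpha, not calcium);
  # halogens/metals with unambiguous two-letter names are recognized explicitly
  two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "SE")
  guess <- substr(nm, 1, 1)
  guess[nm %in% two] <- nm[nm %in% two]
  e[bad] <- guess
  e
}

#' Construct a Structure from an atom table
#'
#' @param atom data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resname}, \code{elety} (atom name), \code{element},
#'   \code{x}, \code{y}, \code{z}, and optionally \code{occ}, \code{b}.
#' @return object of class \code{Structure}: the atom table (with a
#'   \code{resix} residue index column) and a \code{residues} table
#'   (chain, resno, insert, resname, polymer) in atom order.
#' @export
new_structure <- function(atom) {
  need <- c("chain", "resno", "insert", "resname", "elety", "element",
            "x", "y", "z")
  miss <- setdiff(need, names(atom))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z)))
    stop("non-finite atom coordinates")
  atom$insert[is.na(atom$insert)] <- ""
  atom$chain[is.na(atom$chain)] <- ""
  if (is.null(atom$occ)) atom$occ <- 1
  if (is.null(atom$b)) atom$b <- 0
  key <- paste(atom$chain, atom$resno, atom$insert, sep = "\r")
  first <- !duplicated(key)
  residues <- data.frame(chain = atom$chain[first], resno = atom$resno[first],
                         insert = atom$insert[first],
                         resname = atom$resname[first],
                         stringsAsFactors = FALSE)
  residues$polymer <- polymer_class(residues$resname)
  if (anyDuplicated(paste(residues$chain, residues$resno, residues$insert)))
    stop("residue identity (chain, resno, insert) not unique")
  atom$resix <- match(key, key[first])
  structure(list(atom = atom, residues = residues), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atom), nrow(x$residues),
              length(unique(x$residues$chain))))
  tb <- table(x$residues$polymer)
  cat("  residues by class:",
      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Residue labels in author numbering ("chain:resno[insert]")
#' @param structure a \code{Structure}
#' @param idx residue indices (default all)
#' @export
residue_labels <- function(structure, idx = seq_len(nrow(structure$residues))) {
  r <- structure$residues[idx, , drop = FALSE]
  paste0(r$chain, ":", r$resno, ifelse(r$insert == "", "", r$insert))
}

resolve_altloc <- function(atom) {
  if (is.null(atom$alt)) return(atom)
  atom$alt[is.na(atom$alt)] <- ""
  amb <- which(!(atom$alt %in% c("", " ")))
  if (!length(amb)) { atom$alt <- NULL; return(atom) }
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "\r")
  keep <- rep(TRUE, nrow(atom))
  for (k in unique(key[amb])) {
    rows <- which(key == k)
    if (length(rows) < 2) next
    occ <- atom$occ[rows]
    occ[is.na(occ)] <- 1
    best <- rows[order(-occ, atom$alt[rows])][1]  # highest occ, tie -> 'A'
    keep[setdiff(rows, best)] <- FALSE
  }
  atom <- atom[keep, , drop = FALSE]
  atom$alt <- NULL
  atom
}

from_bio3d <- function(pdb) {
  a <- pdb$atom
  atom <- data.frame(chain = a$chain %||% "", resno = a$resno,
                     insert = a$insert %||% "", resname = a$resid,
                     elety = a$elety, alt = a$alt %||% "",
                     x = a$x, y = a$y, z = a$z,
                     occ = a$o %||% 1, b = a$b %||% 0,
                     stringsAsFactors = FALSE)
  atom$insert[is.na(atom$insert)] <- ""
  atom$chain[is.na(atom$chain)] <- ""
  atom$occ[is.na(atom$occ)] <- 1
  atom$b[is.na(atom$b)] <- 0
  atom$element <- guess_element(atom$elety, a$elesy)
  atom <- resolve_altloc(atom)
  new_structure(atom)
}

#' Read a structure from PDB or mmCIF
#'
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties broken towards altloc 'A'); hydrogens are retained when present.
#' Author (PDB "auth") chain ids and residue numbers are preserved verbatim.
#'
#' @param path file path
#' @param format "pdb", "mmcif", or "auto" (by extension)
#' @return a \code{Structure}
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    switch(format,
           pdb = bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                 verbose = FALSE),
           mmcif = bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stop("failed to parse ", format, " file '", path,
         "': no ATOM/HETATM records found", call. = FALSE)
  from_bio3d(pdb)
}

#' Construct an Ensemble
#'
#' @param topology a \code{Structure}
#' @param xyz frames-by-3M coordinate matrix (bio3d convention), Angstrom
#' @param state functional-state label (e.g. "apo", "ATP", "ADP")
#' @return object of class \code{Ensemble}
#' @export
new_ensemble <- function(topology, xyz, state = "") {
  if (!inherits(topology, "Structure")) stop("topology must be a Structure")
  xyz <- as.matrix(xyz)
  m <- nrow(topology$atom)
  if (ncol(xyz) != 3 * m)
    stop("frame atom count (", ncol(xyz) / 3,
         ") does not match topology atom count (", m, ")")
  if (nrow(xyz) < 1) stop("ensemble needs at least one frame")
  structure(list(topology = topology, xyz = xyz, state = state,
                 nframes = nrow(xyz)), class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("Ensemble '%s': %d frames, %d atoms, %d residues\n",
              x$state, x$nframes, nrow(x$topology$atom),
              nrow(x$topology$residues)))
  invisible(x)
}

#' Coordinates of one frame as an M x 3 matrix
#' @param ensemble an \code{Ensemble}
#' @param t frame index
#' @export
get_frame <- function(ensemble, t) {
  if (t < 1 || t > ensemble$nframes) stop("frame index out of range: ", t)
  matrix(ensemble$xyz[t, ], ncol = 3, byrow = TRUE)
}

#' Read a coordinate ensemble
#'
#' Frames are kept in file order and stored in Angstrom; nm-based sources
#' are converted via \code{coord_unit = "nm"}.
#'
#' @param topology a \code{Structure} congruent with the frames
#' @param frames_source path(s) to multi-model PDB or DCD files
#' @param format "auto", "pdb" (multi-model) or "dcd"
#' @param coord_unit unit of the source coordinates
#' @param state functional-state label
#' @return an \code{Ensemble}
#' @export
load_ensemble <- function(topology, frames_source,
                          format = c("auto", "pdb", "dcd"),
                          coord_unit = c("angstrom", "nm"), state = "") {
  format <- match.arg(format)
  coord_unit <- match.arg(coord_unit)
  xyz <- NULL
  for (path in frames_source) {
    if (!file.exists(path)) stop("file not found: ", path)
    fmt <- format
    if (fmt == "auto")
      fmt <- if (tolower(tools::file_ext(path)) == "dcd") "dcd" else "pdb"
    block <- switch(fmt,
      pdb = {
        pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
        x <- pdb$xyz
        if (is.null(dim(x))) x <- matrix(x, nrow = 1)
        unclass(x)
      },
      dcd = unclass(bio3d::read.dcd(path, verbose = FALSE)))
    if (ncol(block) != 3 * nrow(topology$atom))
      stop("atom-count mismatch in '", path, "': frames have ",
           ncol(block) / 3, " atoms, topology has ", nrow(topology$atom))
    xyz <- rbind(xyz, block)
  }
  if (coord_unit == "nm") xyz <- xyz * 10
  new_ensemble(topology, xyz, state = state)
}

#' Write a Structure or Ensemble as (multi-model) PDB
#'
#' @param x a \code{Structure} or \code{Ensemble}
#' @param path output file
#' @export
write_multimodel_pdb <- function(x, path) {
  if (inherits(x, "Structure")) x <- new_ensemble(x, matrix(t(as.matrix(
    x$atom[, c("x", "y", "z")])), nrow = 1))
  if (!inherits(x, "Ensemble")) stop("x must be a Structure or Ensemble")
  a <- x$topology$atom
  name4 <- ifelse(nchar(a$elety) >= 4, substr(a$elety, 1, 4),
                  sprintf(" %-3s", a$elety))
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(x$nframes)) {
    co <- get_frame(x, t)
    lines <- sprintf(
      "ATOM  %5d %4s %-3s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000, name4, substr(a$resname, 1, 3),
      substr(paste0(a$chain, " "), 1, 1), a$resno %% 10000,
      substr(paste0(a$insert, " "), 1, 1),
      co[, 1], co[, 2], co[, 3], a$occ, a$b, a$element)
    writeLines(sprintf("MODEL     %4d", t), con)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
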