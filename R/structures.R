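## Protein structures: a light container for single-chain coordinate sets.
##
## A `hddr_structure` is a list with:
##   id    - character identifier
##   atoms - data.frame(res_index, res_name, atom_name, element, x, y, z)
## Residues are renumbered 1..n on construction; every residue must carry a
## Ca atom and all coordinates must be finite.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1TO3 <- stats::setNames(names(AA3TO1), unname(AA3TO1))

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a structure object
#'
#' @param id character identifier.
#' @param atoms data.frame with columns `res_index`, `res_name`,
#'   `atom_name`, `element`, `x`, `y`, `z`. Residue indices must be
#'   strictly increasing along the chain; they are renumbered to 1..n.
#' @return an object of class `hddr_structure`.
#' @export
new_structure <- function(id, atoms) {
  stopifnot(is.character(id), length(id) == 1L)
  need <- c("res_index", "res_name", "atom_name", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms data.frame must have columns: ", paste(need, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  ridx <- atoms$res_index
  ord <- unique(ridx)
  if (any(diff(ord) <= 0))
    stop("residue indices must be strictly increasing")
  ## renumber 1..n preserving order
  atoms$res_index <- match(ridx, ord)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in structure '", id, "'")
  byres <- split(atoms$atom_name, atoms$res_index)
  no_ca <- names(byres)[!vapply(byres, function(a) "CA" %in% a, logical(1))]
  if (length(no_ca))
    stop("residue(s) missing CA atom: ", paste(no_ca, collapse = ", "))
  structure(list(id = id, atoms = atoms), class = "hddr_structure")
}

#' @export
print.hddr_structure <- function(x, ...) {
  cat(sprintf("<hddr_structure '%s': %d residues, %d atoms>\n",
              x$id, n_residues(x), nrow(x$atoms)))
  invisible(x)
}

#' Number of residues in a structure
#' @param s a `hddr_structure`.
#' @export
n_residues <- function(s) length(unique(s$atoms$res_index))

#' Coordinate matrix of a structure
#' @param s a `hddr_structure`.
#' @param atom_name optional atom name filter (e.g. "CA").
#' @return numeric matrix with one row per atom, columns x, y, z.
#' @export
coords <- function(s, atom_name = NULL) {
  a <- s$atoms
  if (!is.null(atom_name)) a <- a[a$atom_name %in% atom_name, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

#' Replace the coordinates of a structure
#' @param s a `hddr_structure`.
#' @param xyz numeric matrix, one row per atom in `s` order.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms), ncol(xyz) == 3L)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' One-letter amino-acid sequence of a structure
#' @param s a `hddr_structure`.
#' @return single character string.
#' @export
structure_sequence <- function(s) {
  a <- s$atoms
  res <- a$res_name[match(seq_len(n_residues(s)), a$res_index)]
  one <- AA3TO1[res]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

## logical: which atoms are side-chain (not N/CA/C/O)
is_sidechain <- function(s) !(s$atoms$atom_name %in% BACKBONE_ATOMS)

#' Read a single-chain PDB-format coordinate file
#'
#' Parses ATOM records from a PDB file into a [new_structure()] object.
#' HETATM records and waters are dropped; alternate locations are resolved
#' to the highest-occupancy copy (first wins on ties). Multi-chain files
#' and insertion codes are rejected.
#'
#' @param path file path.
#' @param format only `"pdb"` is supported.
#' @param id identifier for the returned structure; defaults to the file
#'   base name.
#' @return a `hddr_structure`.
#' @export
parse_structure <- function(path, format = "pdb", id = NULL) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- which(trimws(rec) == "ATOM")
  if (!length(keep)) stop("no ATOM records in ", path)
  ln <- lines[keep]
  parse_num <- function(str, what, lineno) {
    v <- suppressWarnings(as.numeric(str))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("unparseable ", what, " in PDB record at line ", lineno[bad[1]])
    v
  }
  fields <- list(
    atom_name = trimws(substr(ln, 13, 16)),
    altloc    = substr(ln, 17, 17),
    res_name  = trimws(substr(ln, 18, 20)),
    chain     = substr(ln, 22, 22),
    res_seq   = trimws(substr(ln, 23, 26)),
    icode     = substr(ln, 27, 27),
    x = substr(ln, 31, 38), y = substr(ln, 39, 46), z = substr(ln, 47, 54),
    occ = substr(ln, 55, 60),
    element = trimws(substr(ln, 77, 78)))
  drop <- fields$res_name %in% c("HOH", "WAT")
  if (any(drop)) {
    keep2 <- !drop
    fields <- lapply(fields, `[`, keep2)
    keep <- keep[keep2]
  }
  if (length(unique(fields$chain)) > 1L)
    stop("multi-chain PDB files are not supported (chains: ",
         paste(unique(fields$chain), collapse = ", "), ")")
  if (any(fields$icode != " "))
    stop("insertion codes are not supported (line ",
         keep[which(fields$icode != " ")[1]], ")")
  res_seq <- suppressWarnings(as.integer(fields$res_seq))
  if (anyNA(res_seq))
    stop("unparseable residue number at line ", keep[which(is.na(res_seq))[1]])
  atoms <- data.frame(
    res_index = res_seq,
    res_name  = fields$res_name,
    atom_name = fields$atom_name,
    element   = ifelse(fields$element == "",
                       substr(fields$atom_name, 1, 1), fields$element),
    x = parse_num(fields$x, "x coordinate", keep),
    y = parse_num(fields$y, "y coordinate", keep),
    z = parse_num(fields$z, "z coordinate", keep),
    stringsAsFactors = FALSE)
  ## altloc resolution: highest occupancy per (residue, atom name)
  altloc <- fields$altloc
  if (any(altloc != " ")) {
    occ <- suppressWarnings(as.numeric(fields$occ))
    occ[is.na(occ)] <- 1
    key <- paste(atoms$res_index, atoms$atom_name)
    best <- tapply(seq_len(nrow(atoms)), key, function(i) i[which.max(occ[i])])
    sel <- sort(unlist(best, use.names = FALSE))
    atoms <- atoms[sel, , drop = FALSE]
  }
  if (!all(diff(unique(atoms$res_index)) > 0))
    stop("residue numbering not strictly increasing in ", path)
  new_structure(id %||% sub("\\.[^.]*$", "", basename(path)), atoms)
}

#' Write a structure as a PDB-format file
#'
#' @param s a `hddr_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  name_fmt <- ifelse(nchar(a$atom_name) < 4L,
                     sprintf(" %-3s", a$atom_name),
                     a$atom_name)
  lines <- sprintf(
    "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name_fmt, a$res_name, a$res_index,
    a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
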