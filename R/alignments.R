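## Alignments: pairwise and joined (one target against U templates).
##
## Gap character is "-". A "match column" is a column where both the target
## and a template carry a residue; those columns define the atom
## equivalences used to derive restraints.

#' Construct a pairwise target-template alignment
#'
#' @param target_id,template_id sequence identifiers.
#' @param target_seq,template_seq gapped sequences (same length).
#' @return object of class `hddr_pairwise_alignment`.
#' @export
new_pairwise_alignment <- function(target_id, template_id,
                                   target_seq, template_seq) {
  if (nchar(target_seq) != nchar(template_seq))
    stop("aligned sequences have different lengths (", nchar(target_seq),
         " vs ", nchar(template_seq), ")")
  ungap <- function(x) gsub("-", "", x, fixed = TRUE)
  if (nchar(ungap(target_seq)) == 0L || nchar(ungap(template_seq)) == 0L)
    stop("all-gap sequence in alignment ", target_id, "/", template_id)
  structure(list(target_id = target_id, template_id = template_id,
                 target_seq = target_seq, template_seq = template_seq),
            class = "hddr_pairwise_alignment")
}

#' Construct a joined (multi-template) alignment
#'
#' Joins U pairwise alignments sharing the same target sequence.
#'
#' @param target_id target identifier.
#' @param alignments list of `hddr_pairwise_alignment`.
#' @return object of class `hddr_joined_alignment`.
#' @export
new_joined_alignment <- function(target_id, alignments) {
  stopifnot(length(alignments) >= 1L)
  ungap <- function(x) gsub("-", "", x, fixed = TRUE)
  tseqs <- vapply(alignments, function(a) ungap(a$target_seq), character(1))
  if (length(unique(tseqs)) != 1L)
    stop("pairwise alignments do not share the same target sequence")
  ids <- vapply(alignments, function(a) a$template_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate template identifiers: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  structure(list(target_id = target_id, alignments = alignments),
            class = "hddr_joined_alignment")
}

#' @export
print.hddr_joined_alignment <- function(x, ...) {
  cat(sprintf("<hddr_joined_alignment '%s': %d template(s)>\n",
              x$target_id, length(x$alignments)))
  invisible(x)
}

## Internal: split FASTA-ish text into (name, sequence) records.
read_fasta_records <- function(lines, marker = ">") {
  hdr <- grep(paste0("^", marker), lines)
  if (!length(hdr)) stop("no sequence records found")
  ends <- c(hdr[-1] - 1L, length(lines))
  lapply(seq_along(hdr), function(k) {
    name <- sub(paste0("^", marker, "\\s*"), "", lines[hdr[k]])
    seq <- paste(lines[(hdr[k] + 1L):ends[k]], collapse = "")
    list(name = name, seq = seq)
  })
}

#' Read a target-template alignment file
#'
#' Supports PIR (`format = "pir"`) and gapped/aligned FASTA
#' (`format = "afasta"`). The first entry is taken as the target and every
#' further entry as a template; all gapped sequences must have equal
#' length. Returns a joined alignment (U = number of templates).
#'
#' @param path file path.
#' @param format `"pir"` or `"afasta"`; default guesses from the extension.
#' @return a `hddr_joined_alignment`.
#' @export
parse_alignment <- function(path, format = c("auto", "pir", "afasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.pir$|\\.ali$", path)) "pir" else "afasta"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "pir") {
    ## PIR record = >P1;name / description line / sequence lines ending '*'
    hdr <- grep("^>P1;", lines)
    if (!length(hdr)) stop("no PIR records found in ", path)
    ends <- c(hdr[-1] - 1L, length(lines))
    recs <- lapply(seq_along(hdr), function(k) {
      name <- sub("^>P1;\\s*", "", lines[hdr[k]])
      if (hdr[k] + 1L > ends[k]) stop("truncated PIR record: ", name)
      seq <- paste(lines[(hdr[k] + 2L):ends[k]], collapse = "")
      seq <- gsub("\\*\\s*$", "", seq)
      list(name = trimws(name), seq = gsub("\\s", "", seq))
    })
  } else {
    recs <- read_fasta_records(lines, marker = ">")
    recs <- lapply(recs, function(r)
      list(name = trimws(sub("\\s.*$", "", r$name)), seq = gsub("\\s", "", r$seq)))
  }
  if (length(recs) < 2L)
    stop("alignment must contain one target and at least one template")
  nm <- vapply(recs, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate identifiers in alignment: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  len <- vapply(recs, function(r) nchar(r$seq), integer(1))
  if (length(unique(len)) != 1L)
    stop("gapped sequences differ in length: ", paste(len, collapse = ", "))
  target <- recs[[1]]
  aln <- lapply(recs[-1], function(r)
    new_pairwise_alignment(target$name, r$name, target$seq, r$seq))
  new_joined_alignment(target$name, aln)
}

#' Write a joined alignment in PIR format
#' @param aln a `hddr_joined_alignment`.
#' @param path output file path.
#' @export
write_alignment_pir <- function(aln, path) {
  out <- character(0)
  emit <- function(name, kind, seq)
    c(sprintf(">P1;%s", name), sprintf("%s:%s::::::::", kind, name),
      paste0(seq, "*"))
  out <- c(out, emit(aln$target_id, "sequence", aln$alignments[[1]]$target_seq))
  for (a in aln$alignments)
    out <- c(out, emit(a$template_id, "structureX", a$template_seq))
  writeLines(out, path)
  invisible(path)
}

#' Residue correspondence implied by a pairwise alignment
#'
#' For every match column (both sequences non-gap) returns the 1-based
#' residue index of the target and template residue. Errors if either
#' gapped sequence disagrees with the residue sequence of the supplied
#' structure.
#'
#' @param aln a `hddr_pairwise_alignment`.
#' @param target,template `hddr_structure` objects (optional; when given,
#'   sequences are validated against the alignment).
#' @return data.frame with columns `target_res`, `template_res`.
#' @export
residue_correspondence <- function(aln, target = NULL, template = NULL) {
  tg <- strsplit(aln$target_seq, "")[[1]]
  tp <- strsplit(aln$template_seq, "")[[1]]
  check <- function(gapped, s, what) {
    ungapped <- gapped[gapped != "-"]
    sseq <- strsplit(structure_sequence(s), "")[[1]]
    if (length(ungapped) != length(sseq))
      stop(what, " alignment length ", length(ungapped),
           " != structure length ", length(sseq))
    bad <- which(ungapped != sseq)
    if (length(bad))
      stop(what, " sequence mismatch at residue ", bad[1], " ('",
           ungapped[bad[1]], "' vs '", sseq[bad[1]], "')")
  }
  if (!is.null(target)) check(tg, target, "target")
  if (!is.null(template)) check(tp, template, "template")
  ti <- cumsum(tg != "-")
  pi <- cumsum(tp != "-")
  m <- tg != "-" & tp != "-"
  data.frame(target_res = ti[m], template_res = pi[m])
}

#' Column-wise local sequence identity in a window
#'
#' Fraction of identical residue pairs in a window of aligned columns
#' centred on each target residue; used by the similarity template
#' weighting scheme.
#'
#' @param aln a `hddr_pairwise_alignment`.
#' @param window odd window width in columns (default 11).
#' @return numeric vector, one value per target residue (NA where the
#'   target residue is aligned to a gap).
#' @export
local_identity <- function(aln, window = 11L) {
  tg <- strsplit(aln$target_seq, "")[[1]]
  tp <- strsplit(aln$template_seq, "")[[1]]
  n <- length(tg)
  half <- (window - 1L) %/% 2L
  ident <- as.numeric(tg == tp & tg != "-")
  out_col <- vapply(seq_len(n), function(c) {
    w <- max(1L, c - half):min(n, c + half)
    mean(ident[w])
  }, numeric(1))
  ## map columns to target residues
  ti <- cumsum(tg != "-")
  res_ids <- ti[tg != "-"]
  vals <- out_col[tg != "-"]
  out <- rep(NA_real_, max(res_ids))
  out[res_ids] <- vals
  out
}
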