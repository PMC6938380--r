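## Synthetic native/template corpus generator.
##
## Natives are built from ideal secondary-structure geometry with reduced
## side chains (CB plus one CG pseudo-atom standing in for the side-chain
## centroid); templates are natives deformed by rigid sub-segment motions
## plus per-atom jitter, rescaled until the superposed Calpha RMSD hits a
## requested divergence, so |delta d_n| profiles carry the spatial
## autocorrelation real homolog pairs show. Alignments are identity
## alignments with a controlled fraction of +/-1-residue register shifts.

## residue alphabet: G has no side chain, A only CB, the rest CB+CG
SYN_ALPHABET <- c("G", "A", "L", "S", "V", "E", "K", "F", "D", "T")

#' Specification for one synthetic target
#'
#' @param length chain length in residues (10..120).
#' @param fold `"helix"`, `"hairpin"` or `"mixed"`.
#' @param divergence target template-vs-native Calpha RMSD (A); a vector
#'   gives one divergence per template.
#' @param aln_error fraction of target residues mis-registered by one
#'   position in the alignment (0..0.5).
#' @param n_templates number of templates.
#' @param seed integer seed.
#' @return a `hddr_toy_spec` list.
#' @export
toy_spec <- function(length = 30L, fold = c("helix", "hairpin", "mixed"),
                     divergence = 1.5, aln_error = 0, n_templates = 1L,
                     seed = 1L) {
  fold <- match.arg(fold)
  stopifnot(length >= 10L, length <= 120L, all(divergence >= 0),
            aln_error >= 0, aln_error <= 0.5, n_templates >= 1L)
  if (base::length(divergence) == 1L)
    divergence <- divergence * seq(1, by = 0.5, length.out = n_templates)
  stopifnot(base::length(divergence) == n_templates)
  structure(list(length = as.integer(length), fold = fold,
                 divergence = divergence, aln_error = aln_error,
                 n_templates = as.integer(n_templates),
                 seed = as.integer(seed)),
            class = "hddr_toy_spec")
}

## phi/psi per residue for a fold
fold_torsions <- function(fold, n) {
  helix <- c(-57, -47); strand <- c(-139, 135); turn <- c(-60, -30)
  tor <- switch(fold,
    helix = matrix(helix, n, 2, byrow = TRUE),
    hairpin = {
      h <- n %/% 2
      rbind(matrix(strand, h - 1, 2, byrow = TRUE),
            matrix(turn, 2, 2, byrow = TRUE),
            matrix(strand, n - h - 1, 2, byrow = TRUE))
    },
    mixed = {
      h <- n %/% 2
      rbind(matrix(helix, h, 2, byrow = TRUE),
            matrix(turn, 2, 2, byrow = TRUE),
            matrix(strand, n - h - 2, 2, byrow = TRUE))
    },
    extended = matrix(c(-120, 120), n, 2, byrow = TRUE))
  tor[seq_len(n), , drop = FALSE]
}

#' Build an ideal-geometry peptide structure
#'
#' Constructs a reduced-atom chain (N, CA, C, O per residue; CB except
#' glycine; CG pseudo side-chain atom except glycine/alanine) from ideal
#' bond lengths and angles with fold-specific phi/psi torsions.
#'
#' @param sequence one-letter amino-acid string.
#' @param fold `"helix"`, `"hairpin"`, `"mixed"` or `"extended"`.
#' @param id structure identifier.
#' @return a `hddr_structure`.
#' @export
build_peptide <- function(sequence, fold = "helix", id = "peptide") {
  seq1 <- strsplit(sequence, "")[[1]]
  n <- length(seq1)
  stopifnot(n >= 2L)
  tor <- fold_torsions(fold, n)
  phi <- tor[, 1]; psi <- tor[, 2]
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3); C <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(IDEAL_BONDS[["N-CA"]], 0, 0)
  ang <- IDEAL_ANGLES_DEG[["N-CA-C"]] * pi / 180
  C[1, ] <- CA[1, ] + IDEAL_BONDS[["CA-C"]] *
    c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1L)) {
    Nn <- place_atom(N[i, ], CA[i, ], C[i, ], IDEAL_BONDS[["C-N"]],
                     IDEAL_ANGLES_DEG[["CA-C-N"]], psi[i])
    CAn <- place_atom(CA[i, ], C[i, ], Nn, IDEAL_BONDS[["N-CA"]],
                      IDEAL_ANGLES_DEG[["C-N-CA"]], 180)
    Cn <- place_atom(C[i, ], Nn, CAn, IDEAL_BONDS[["CA-C"]],
                     IDEAL_ANGLES_DEG[["N-CA-C"]], phi[i + 1])
    N[i + 1L, ] <- Nn; CA[i + 1L, ] <- CAn; C[i + 1L, ] <- Cn
  }
  rows <- list()
  for (i in seq_len(n)) {
    res3 <- AA1TO3[[seq1[i]]]
    O <- place_atom(N[i, ], CA[i, ], C[i, ], IDEAL_BONDS[["C-O"]],
                    IDEAL_ANGLES_DEG[["CA-C-O"]], psi[i] + 180)
    at <- rbind(
      data.frame(atom_name = "N", element = "N", x = N[i, 1], y = N[i, 2], z = N[i, 3]),
      data.frame(atom_name = "CA", element = "C", x = CA[i, 1], y = CA[i, 2], z = CA[i, 3]),
      data.frame(atom_name = "C", element = "C", x = C[i, 1], y = C[i, 2], z = C[i, 3]),
      data.frame(atom_name = "O", element = "O", x = O[1], y = O[2], z = O[3]))
    if (seq1[i] != "G") {
      CB <- place_atom(C[i, ], N[i, ], CA[i, ], IDEAL_BONDS[["CA-CB"]],
                       IDEAL_ANGLES_DEG[["N-CA-CB"]], 122.5)
      at <- rbind(at, data.frame(atom_name = "CB", element = "C",
                                 x = CB[1], y = CB[2], z = CB[3]))
      if (seq1[i] != "A") {
        CG <- place_atom(N[i, ], CA[i, ], CB, IDEAL_BONDS[["CB-CG"]],
                         IDEAL_ANGLES_DEG[["CA-CB-CG"]], -60)
        at <- rbind(at, data.frame(atom_name = "CG", element = "C",
                                   x = CG[1], y = CG[2], z = CG[3]))
      }
    }
    at$res_index <- i
    at$res_name <- res3
    rows[[i]] <- at
  }
  atoms <- do.call(rbind, rows)
  new_structure(id, atoms[, c("res_index", "res_name", "atom_name",
                              "element", "x", "y", "z")])
}

## deform a structure: rigid sub-segment rotations/translations plus
## per-atom jitter applied to a random ~70% of atoms. The unjittered
## atoms form conserved patches whose intra-segment distances survive the
## rigid moves exactly, so the |delta d_n| distribution keeps the strong
## near-zero mode real homolog pairs show.
deform_structure <- function(s, amplitude, seg_len = 8L, jitter_frac = 0.7) {
  X <- coords(s)
  res <- s$atoms$res_index
  nres <- max(res)
  breaks <- seq(1L, nres, by = seg_len)
  for (b in breaks) {
    rows <- which(res >= b & res < b + seg_len)
    if (length(rows) < 2L) next
    ctr <- colMeans(X[rows, , drop = FALSE])
    ax <- stats::rnorm(3); ax <- ax / vnorm(ax)
    theta <- stats::rnorm(1, 0, 0.04 * amplitude)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
    shift <- stats::rnorm(3, 0, 0.45 * amplitude)
    X[rows, ] <- sweep(sweep(X[rows, , drop = FALSE], 2, ctr) %*% t(R),
                       2, ctr + shift, `+`)
  }
  moved <- which(stats::runif(nrow(X)) < jitter_frac)
  X[moved, ] <- X[moved, , drop = FALSE] +
    matrix(stats::rnorm(3 * length(moved), 0, 0.35 * amplitude),
           length(moved), 3)
  set_coords(s, X)
}

## identity alignment with `err` fraction of +1 register shifts
shifted_alignment <- function(target_id, template_id, seq1, err, seed) {
  n <- nchar(seq1)
  n_shift <- round(err * n)
  tchars <- strsplit(seq1, "")[[1]]
  if (n_shift == 0) {
    return(new_pairwise_alignment(target_id, template_id, seq1, seq1))
  }
  set.seed(seed)
  ## choose shift segments of length <= 3 away from the termini
  shifted <- logical(n)
  guard <- 2L
  tries <- 0L
  while (sum(shifted) < n_shift && tries < 200L) {
    tries <- tries + 1L
    L <- min(sample(1:3, 1), n_shift - sum(shifted))
    s <- sample((guard + 1L):(n - guard - L), 1)
    win <- s:(s + L - 1L)
    ## keep a buffer so segments do not touch
    if (any(shifted[max(1, s - 2L):min(n, s + L + 1L)])) next
    shifted[win] <- TRUE
  }
  ## build gapped rows: a shifted run [s..e] aligns target i to template i+1,
  ## consuming template residue s unaligned before the run and leaving a
  ## target gap column, then re-synchronising after the run
  tg <- character(0); tp <- character(0)
  i <- 1L
  while (i <= n) {
    if (!shifted[i]) {
      tg <- c(tg, tchars[i]); tp <- c(tp, tchars[i]); i <- i + 1L
    } else {
      e <- i
      while (e < n && shifted[e + 1L]) e <- e + 1L
      tg <- c(tg, "-", tchars[i:e], tchars[e + 1L])
      tp <- c(tp, tchars[i], tchars[(i:e) + 1L], "-")
      i <- e + 2L
    }
  }
  new_pairwise_alignment(target_id, template_id,
                         paste(tg, collapse = ""), paste(tp, collapse = ""))
}

#' Generate a synthetic native/template pair
#'
#' Builds a native structure from the spec, derives each template by
#' seeded deformation rescaled until its superposed Calpha RMSD is within
#' 15% of the requested divergence, and emits an identity alignment with
#' the requested fraction of one-residue register shifts.
#'
#' @param spec a [toy_spec()].
#' @return list with `native` (structure), `templates` (list of
#'   structures), `aln` (`hddr_joined_alignment`) and `realized`
#'   (data.frame of realized divergences).
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "hddr_toy_spec"))
  set.seed(spec$seed)
  seq1 <- paste(sample(SYN_ALPHABET, spec$length, replace = TRUE),
                collapse = "")
  native <- build_peptide(seq1, spec$fold, id = sprintf("syn%04d", spec$seed))
  templates <- list(); realized <- numeric(spec$n_templates)
  for (u in seq_len(spec$n_templates)) {
    div <- spec$divergence[u]
    if (div == 0) {
      tmpl <- native
      realized[u] <- 0
    } else {
      amp <- div
      set.seed(derive_seed(spec$seed, u))
      for (it in 1:12) {
        set.seed(derive_seed(spec$seed, u * 100L + it))
        tmpl <- deform_structure(native, amp)
        realized[u] <- superpose_rmsd(coords(tmpl, "CA"),
                                      coords(native, "CA"))$rmsd
        if (abs(realized[u] - div) <= 0.15 * div) break
        amp <- amp * div / max(realized[u], 1e-6)
      }
      if (abs(realized[u] - div) > 0.15 * div)
        stop("could not reach divergence ", div, " A for length ",
             spec$length, " (got ", round(realized[u], 2), " A)")
    }
    tmpl$id <- sprintf("%s_t%d", native$id, u)
    templates[[u]] <- tmpl
  }
  alns <- lapply(seq_len(spec$n_templates), function(u)
    shifted_alignment(native$id, templates[[u]]$id, seq1, spec$aln_error,
                      derive_seed(spec$seed, 7000L + u)))
  list(native = native, templates = templates,
       aln = new_joined_alignment(native$id, alns),
       realized = data.frame(template = seq_len(spec$n_templates),
                             requested = spec$divergence,
                             realized = realized))
}

#' Generate a benchmark corpus on disk
#'
#' Writes native and template PDB files, PIR alignments and a manifest
#' TSV. Deterministic for a fixed seed.
#'
#' @param n_targets number of targets.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed.
#' @param length_range,divergence_range uniform sampling ranges.
#' @param folds candidate folds sampled per target.
#' @param aln_error alignment error rate applied to every target.
#' @param n_templates templates per target.
#' @return the manifest data.frame (also written to
#'   `file.path(out_dir, "manifest.tsv")`).
#' @export
generate_corpus <- function(n_targets, out_dir, seed = 1L,
                            length_range = c(20L, 30L),
                            divergence_range = c(0.8, 2.5),
                            folds = c("helix", "hairpin", "mixed"),
                            aln_error = 0.05, n_templates = 1L) {
  stopifnot(n_targets >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (k in seq_len(n_targets)) {
    sk <- derive_seed(seed, k)
    set.seed(sk)
    spec <- toy_spec(
      length = sample(length_range[1]:length_range[2], 1),
      fold = sample(folds, 1),
      divergence = stats::runif(n_templates, divergence_range[1],
                                divergence_range[2]),
      aln_error = aln_error, n_templates = n_templates, seed = sk)
    pair <- generate_pair(spec)
    npath <- file.path(out_dir, paste0(pair$native$id, ".pdb"))
    write_structure(pair$native, npath)
    tpaths <- vapply(pair$templates, function(t) {
      p <- file.path(out_dir, paste0(t$id, ".pdb"))
      write_structure(t, p); p
    }, character(1))
    apath <- file.path(out_dir, paste0(pair$native$id, ".pir"))
    write_alignment_pir(pair$aln, apath)
    rows[[k]] <- data.frame(
      target = pair$native$id, length = spec$length, fold = spec$fold,
      native_pdb = npath, template_pdbs = paste(tpaths, collapse = ","),
      alignment = apath,
      realized_divergence = paste(round(pair$realized$realized, 3),
                                  collapse = ","),
      aln_error = aln_error, seed = sk)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
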