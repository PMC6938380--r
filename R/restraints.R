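## Homology-derived distance restraints (HDDRs).
##
## Each restraint acts on one model interatomic distance d_m and carries
## one entry per covering template u: the template distance d_t_u, a
## Gaussian standard deviation sigma_u and a mixture weight w_u. The
## restraint pdf is the weighted Gaussian mixture
##   f(d_m) = sum_u w_u N(d_m; d_t_u, sigma_u)
## and its objective-function term is -ln f(d_m); with a single template
## this is the harmonic form (d_m - d_t)^2 / (2 sigma^2) + ln(sigma sqrt(2 pi)).
##
## Four restraint groups are built: CA-CA (Calpha pairs), N-O (backbone
## amide N vs carbonyl O), SCMC (side chain vs main chain) and SCSC
## (side chain vs side chain).

HDDR_GROUPS <- c("CA-CA", "N-O", "SCMC", "SCSC")

#' Default per-group template-distance ceilings (Angstrom)
#'
#' Restraints are only generated for atom pairs whose template distance is
#' below the group ceiling.
#' @export
default_cutoffs <- function() {
  c("CA-CA" = 14, "N-O" = 11, "SCMC" = 6.5, "SCSC" = 6.5)
}

## minimum residue separation per group (covalent neighbours are governed
## by the stereochemical terms, not by HDDRs)
default_min_sep <- function() c("CA-CA" = 2L, "N-O" = 2L, "SCMC" = 1L, "SCSC" = 1L)

#' Gaussian restraint objective term
#'
#' The negative log of a Gaussian density with mean `d_t` and standard
#' deviation `sigma`, evaluated at the model distance `d_m`:
#' `(d_m - d_t)^2 / (2 sigma^2) + ln(sigma * sqrt(2*pi))`. A deviation of
#' exactly one sigma adds exactly 0.5 above the minimum.
#'
#' @param d_m model distance (Angstrom); vectorized.
#' @param d_t template distance (Angstrom).
#' @param sigma Gaussian standard deviation (Angstrom, > 0).
#' @return objective value(s), dimensionless.
#' @export
gaussian_objective_term <- function(d_m, d_t, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  (d_m - d_t)^2 / (2 * sigma^2) + log(sigma * sqrt(2 * pi))
}

#' Multi-template mixture density of a restraint
#'
#' Weighted sum of Gaussian densities, one per template entry. The
#' restraint objective term is `-log()` of this value.
#'
#' @param d_m model distance (Angstrom); vectorized.
#' @param w,d_t,sigma per-template weights, means and standard deviations.
#' @return probability density (1/Angstrom).
#' @export
mixture_density <- function(d_m, w, d_t, sigma) {
  stopifnot(length(w) == length(d_t), length(w) == length(sigma))
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (all(w == 0)) stop("all mixture weights are zero")
  if (abs(sum(w) - 1) > 1e-9) stop("mixture weights must sum to 1")
  vapply(d_m, function(x) sum(w * stats::dnorm(x, d_t, sigma)), numeric(1))
}

#' Template weights for a multi-template restraint
#'
#' Three schemes: `"uniform"` gives every template `1/U`; `"only_lowest"`
#' (OL) gives weight 1 to the template with the smallest sigma and 0 to the
#' rest (ties broken by lowest template index); `"similarity"` makes
#' weights proportional to a local sequence-identity score per template
#' (floored at 0.05 before normalization).
#'
#' @param scheme one of `"uniform"`, `"only_lowest"`, `"similarity"`.
#' @param context for `"only_lowest"` the per-template sigma vector; for
#'   `"similarity"` the per-template local identity scores; for
#'   `"uniform"` any vector of length U (only the length is used).
#' @return numeric weight vector summing to 1.
#' @export
template_weights <- function(scheme = c("uniform", "only_lowest", "similarity"),
                             context) {
  scheme <- match.arg(scheme)
  U <- length(context)
  if (U < 1L) stop("empty template list")
  switch(scheme,
    uniform = rep(1 / U, U),
    only_lowest = {
      w <- numeric(U)
      w[which.min(context)] <- 1  # which.min takes the first on ties
      w
    },
    similarity = {
      s <- pmax(as.numeric(context), 0.05)
      s / sum(s)
    })
}

## Map every atom of the model topology onto template coordinates.
## Returns an n_atoms x 3 matrix with NA rows where the template does not
## cover the atom (unaligned residue or missing atom name).
map_template_atoms <- function(model, template, corr) {
  ma <- model$atoms
  ta <- template$atoms
  out <- matrix(NA_real_, nrow(ma), 3)
  tmpl_res <- corr$template_res[match(ma$res_index, corr$target_res)]
  key_m <- paste(tmpl_res, ma$atom_name)
  key_t <- paste(ta$res_index, ta$atom_name)
  hit <- match(key_m, key_t)
  ok <- !is.na(tmpl_res) & !is.na(hit)
  out[ok, ] <- as.matrix(ta[hit[ok], c("x", "y", "z")])
  out
}

## Candidate atom pairs per group on the model topology.
candidate_pairs <- function(model, min_sep) {
  a <- model$atoms
  sc <- which(!(a$atom_name %in% BACKBONE_ATOMS))
  bb <- which(a$atom_name %in% BACKBONE_ATOMS)
  ca <- which(a$atom_name == "CA")
  nn <- which(a$atom_name == "N")
  oo <- which(a$atom_name == "O")
  res <- a$res_index
  pair_grid <- function(i, j, sep, same_set = FALSE) {
    if (!length(i) || !length(j)) return(cbind(ai = integer(0), aj = integer(0)))
    g <- expand.grid(ai = i, aj = j)
    g <- g[abs(res[g$ai] - res[g$aj]) >= sep, , drop = FALSE]
    if (same_set) g <- g[g$ai < g$aj, , drop = FALSE] else {
      ## unordered pairs from two sets: orient ai < aj, drop duplicates
      swap <- g$ai > g$aj
      tmp <- g$ai[swap]; g$ai[swap] <- g$aj[swap]; g$aj[swap] <- tmp
      g <- unique(g)
    }
    as.matrix(g)
  }
  list(
    "CA-CA" = pair_grid(ca, ca, min_sep[["CA-CA"]], same_set = TRUE),
    "N-O"   = pair_grid(nn, oo, min_sep[["N-O"]]),
    "SCMC"  = pair_grid(sc, bb, min_sep[["SCMC"]]),
    "SCSC"  = pair_grid(sc, sc, min_sep[["SCSC"]], same_set = TRUE))
}

#' Build homology-derived distance restraints
#'
#' For every candidate atom pair in each of the four restraint groups and
#' for every template covering both atoms with a template distance below
#' the group ceiling, emits one restraint entry. Pairs covered by several
#' templates yield multi-template restraints (entries merged over
#' templates). Initial sigmas are `default_sigma`; weights follow
#' `weight_scheme` (similarity weights use an 11-residue identity window).
#'
#' @param aln a `hddr_joined_alignment`.
#' @param templates list of `hddr_structure`, one per alignment entry
#'   (matched by template identifier).
#' @param model_topology a `hddr_structure` giving the target atom set
#'   (its coordinates are ignored).
#' @param cutoffs named per-group distance ceilings; see [default_cutoffs()].
#' @param min_sep named per-group minimum residue separations.
#' @param default_sigma initial sigma for every entry (Angstrom).
#' @param weight_scheme `"uniform"`, `"only_lowest"` or `"similarity"`.
#' @return object of class `hddr_restraint_set`: a list with an `entries`
#'   data.frame (rid, group, ai, aj, res_i, atom_i, res_j, atom_j, u,
#'   template_id, d_t, sigma, w) and provenance fields.
#' @export
build_hddrs <- function(aln, templates, model_topology,
                        cutoffs = default_cutoffs(),
                        min_sep = default_min_sep(),
                        default_sigma = 1.0,
                        weight_scheme = c("uniform", "only_lowest", "similarity")) {
  weight_scheme <- match.arg(weight_scheme)
  tmpl_ids <- vapply(aln$alignments, function(a) a$template_id, character(1))
  have_ids <- vapply(templates, function(s) s$id, character(1))
  idx <- match(tmpl_ids, have_ids)
  if (anyNA(idx))
    stop("template structure(s) missing for: ",
         paste(tmpl_ids[is.na(idx)], collapse = ", "))
  templates <- templates[idx]
  if (structure_sequence(model_topology) !=
      gsub("-", "", aln$alignments[[1]]$target_seq, fixed = TRUE))
    stop("model topology sequence does not match alignment target sequence")

  maps <- vector("list", length(templates))
  sims <- vector("list", length(templates))
  for (u in seq_along(templates)) {
    corr <- residue_correspondence(aln$alignments[[u]], model_topology,
                                   templates[[u]])
    maps[[u]] <- map_template_atoms(model_topology, templates[[u]], corr)
    sims[[u]] <- local_identity(aln$alignments[[u]])
  }

  pairs <- candidate_pairs(model_topology, min_sep)
  a <- model_topology$atoms
  entries <- list()
  for (grp in HDDR_GROUPS) {
    pr <- pairs[[grp]]
    if (!nrow(pr)) next
    for (u in seq_along(templates)) {
      M <- maps[[u]]
      dxyz <- M[pr[, "ai"], , drop = FALSE] - M[pr[, "aj"], , drop = FALSE]
      d_t <- sqrt(rowSums(dxyz^2))
      sel <- which(is.finite(d_t) & d_t <= cutoffs[[grp]] & d_t > 0)
      if (!length(sel)) next
      ai <- pr[sel, "ai"]; aj <- pr[sel, "aj"]
      entries[[length(entries) + 1L]] <- data.frame(
        rid = paste(grp, ai, aj, sep = ":"),
        group = grp, ai = ai, aj = aj,
        res_i = a$res_index[ai], atom_i = a$atom_name[ai],
        res_j = a$res_index[aj], atom_j = a$atom_name[aj],
        u = u, template_id = tmpl_ids[u],
        d_t = d_t[sel], sigma = default_sigma, w = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(entries)) {
    warning("empty restraint set")
    ent <- data.frame(rid = character(0), group = character(0),
                      ai = integer(0), aj = integer(0),
                      res_i = integer(0), atom_i = character(0),
                      res_j = integer(0), atom_j = character(0),
                      u = integer(0), template_id = character(0),
                      d_t = numeric(0), sigma = numeric(0), w = numeric(0))
  } else {
    ent <- do.call(rbind, entries)
    ent <- ent[order(ent$group, ent$ai, ent$aj, ent$u), , drop = FALSE]
    rownames(ent) <- NULL
  }
  rs <- structure(list(entries = ent, target_id = aln$target_id,
                       template_ids = tmpl_ids,
                       cutoffs = cutoffs, min_sep = min_sep,
                       similarity = sims),
                  class = "hddr_restraint_set")
  set_weights(rs, weight_scheme)
}

#' @export
print.hddr_restraint_set <- function(x, ...) {
  tab <- table(factor(unique_restraints(x)$group, levels = HDDR_GROUPS))
  cat(sprintf("<hddr_restraint_set '%s': %d restraints (%s), %d entries>\n",
              x$target_id, n_restraints(x),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", "),
              nrow(x$entries)))
  invisible(x)
}

#' Number of distinct restraints in a set
#' @param rs a `hddr_restraint_set`.
#' @export
n_restraints <- function(rs) length(unique(rs$entries$rid))

## one row per restraint (first entry)
unique_restraints <- function(rs) {
  e <- rs$entries
  e[!duplicated(e$rid), c("rid", "group", "ai", "aj"), drop = FALSE]
}

#' Recompute mixture weights of a restraint set
#'
#' @param rs a `hddr_restraint_set`.
#' @param scheme weighting scheme, see [template_weights()].
#' @return the updated restraint set.
#' @export
set_weights <- function(rs, scheme = c("uniform", "only_lowest", "similarity")) {
  scheme <- match.arg(scheme)
  e <- rs$entries
  if (!nrow(e)) return(rs)
  sim_of <- function(rows) {
    vapply(seq_along(rows), function(k) {
      r <- rows[k]
      li <- rs$similarity[[e$u[r]]]
      mean(c(li[e$res_i[r]], li[e$res_j[r]]), na.rm = TRUE)
    }, numeric(1))
  }
  idx <- split(seq_len(nrow(e)), e$rid)
  w <- numeric(nrow(e))
  for (rows in idx) {
    ctx <- switch(scheme,
      uniform = e$u[rows],
      only_lowest = e$sigma[rows],
      similarity = sim_of(rows))
    w[rows] <- template_weights(scheme, ctx)
  }
  rs$entries$w <- w
  rs
}

#' Set a uniform sigma on every restraint entry
#' @param rs a `hddr_restraint_set`.
#' @param sigma sigma value in Angstrom (> 0).
#' @export
set_uniform_sigma <- function(rs, sigma) {
  stopifnot(sigma > 0)
  rs$entries$sigma <- sigma
  rs
}

#' Write a restraint set as TSV
#'
#' One row per restraint entry; columns `group, res_i, atom_i, res_j,
#' atom_j, u, template_id, d_t, sigma, w`.
#'
#' @param rs a `hddr_restraint_set`.
#' @param path output file path.
#' @export
write_restraints <- function(rs, path) {
  cols <- c("group", "res_i", "atom_i", "res_j", "atom_j",
            "u", "template_id", "d_t", "sigma", "w")
  ## native-derived columns ride along when present (optimal-sigma output)
  cols <- c(cols, intersect(c("d_n", "abs_ddn"), names(rs$entries)))
  utils::write.table(rs$entries[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a restraint TSV back against a model topology
#'
#' @param path TSV path written by [write_restraints()].
#' @param model_topology the `hddr_structure` the atom references resolve
#'   against.
#' @return a `hddr_restraint_set`.
#' @export
read_restraints <- function(path, model_topology) {
  e <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  a <- model_topology$atoms
  key <- paste(a$res_index, a$atom_name)
  e$ai <- match(paste(e$res_i, e$atom_i), key)
  e$aj <- match(paste(e$res_j, e$atom_j), key)
  if (anyNA(e$ai) || anyNA(e$aj))
    stop("restraint atom not present in model topology")
  e$rid <- paste(e$group, e$ai, e$aj, sep = ":")
  structure(list(entries = e, target_id = model_topology$id,
                 template_ids = unique(e$template_id),
                 cutoffs = default_cutoffs(), min_sep = default_min_sep(),
                 similarity = NULL),
            class = "hddr_restraint_set")
}
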