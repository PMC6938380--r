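## Model quality assessment: optimal superposition RMSD, GDT-HA and lDDT.
##
## GDT-HA averages, over the 0.5/1/2/4 A cutoffs, the largest fraction of
## Calpha atoms that can be brought simultaneously within the cutoff by
## any rigid superposition; the search is seeded from contiguous fragments
## and iteratively extended. lDDT is superposition-free: it scores the
## fraction of native interatomic distances (different residues, within a
## 15 A inclusion radius) preserved in the model, averaged over the same
## four thresholds.

GDT_CUTOFFS <- c(0.5, 1, 2, 4)
LDDT_THRESHOLDS <- c(0.5, 1, 2, 4)
LDDT_RADIUS <- 15

#' Optimal rigid superposition and RMSD (Kabsch)
#'
#' Least-squares superposes `P` onto `Q` and returns the RMSD plus the
#' rigid transform (rotation `R`, translation `t`, so `P %*% R + t`
#' matches `Q`).
#'
#' @param P,Q corresponded coordinate matrices (n x 3, n >= 3).
#' @return list with `rmsd`, `R`, `t`, `P_fit`.
#' @export
superpose_rmsd <- function(P, Q) {
  stopifnot(is.matrix(P), is.matrix(Q), all(dim(P) == dim(Q)))
  if (nrow(P) < 3L) stop("need at least 3 corresponded points")
  fit <- kabsch(P, Q)
  if (is.null(fit)) stop("degenerate (collinear) point set")
  fit$rmsd <- sqrt(mean(rowSums((fit$P_fit - Q)^2)))
  fit
}

## Kabsch core; returns NULL on a degenerate (rank < 2) configuration
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)) {
    ## rank-deficient: identical/collinear sets. Identical sets are fine.
    if (max(abs(Pc)) < 1e-9 && max(abs(Qc)) < 1e-9) {
      R <- diag(3)
    } else if (sv$d[1] < 1e-12) {
      return(NULL)
    } else return(NULL)
  } else {
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  }
  t <- cq - as.vector(cp %*% R)
  list(R = R, t = t, P_fit = sweep(P %*% R, 2, t, `+`))
}

## largest fraction of points within `cutoff` after iterative superposition
## refinement from a seed subset
gdt_fraction <- function(P, Q, cutoff, seeds, max_iter = 5L) {
  n <- nrow(P)
  best <- 0
  for (seed in seeds) {
    sub <- seed
    last <- integer(0)
    for (it in seq_len(max_iter)) {
      if (length(sub) < 3L) break
      fit <- kabsch(P[sub, , drop = FALSE], Q[sub, , drop = FALSE])
      if (is.null(fit)) break
      Pf <- sweep(P %*% fit$R, 2, fit$t, `+`)
      d <- sqrt(rowSums((Pf - Q)^2))
      hit <- which(d <= cutoff)
      best <- max(best, length(hit) / n)
      if (identical(hit, last) || length(hit) < 3L) break
      last <- hit
      sub <- hit
    }
  }
  best
}

gdt_seeds <- function(n, frag_lengths = c(3L, 5L, 7L)) {
  seeds <- list(seq_len(n))  # global superposition seed
  for (L in frag_lengths) {
    if (n < L) next
    for (s in seq_len(n - L + 1L)) seeds[[length(seeds) + 1L]] <- s:(s + L - 1L)
  }
  seeds
}

#' GDT-HA score of a model against its native structure
#'
#' Mean over the 0.5, 1, 2 and 4 A cutoffs of the maximum fraction of
#' Calpha atoms simultaneously within the cutoff under a rigid
#' superposition found by seeded iterative search (seeds: the global
#' least-squares fit and every contiguous 3/5/7-residue fragment).
#'
#' @param model,native corresponded `hddr_structure` objects (same residue
#'   count) or n x 3 Calpha coordinate matrices.
#' @param cutoffs distance cutoffs (A).
#' @return score in [0, 1].
#' @export
gdt_ha <- function(model, native, cutoffs = GDT_CUTOFFS) {
  P <- if (inherits(model, "hddr_structure")) coords(model, "CA") else model
  Q <- if (inherits(native, "hddr_structure")) coords(native, "CA") else native
  stopifnot(nrow(P) == nrow(Q))
  if (nrow(P) < 4L) stop("need at least 4 Calpha atoms for GDT-HA")
  seeds <- gdt_seeds(nrow(P))
  mean(vapply(cutoffs, function(cc) gdt_fraction(P, Q, cc, seeds), numeric(1)))
}

#' lDDT score of a model against its native structure
#'
#' Superposition-free local distance difference test (distance component
#' only): over all native heavy-atom pairs from different residues with a
#' native distance below the inclusion radius, the fraction whose model
#' distance differs by less than each threshold, averaged over the
#' thresholds.
#'
#' @param model,native corresponded `hddr_structure` objects sharing the
#'   same atom list.
#' @param thresholds difference thresholds (A).
#' @param radius inclusion radius on native distances (A).
#' @return score in [0, 1].
#' @export
lddt <- function(model, native, thresholds = LDDT_THRESHOLDS,
                 radius = LDDT_RADIUS) {
  stopifnot(nrow(model$atoms) == nrow(native$atoms))
  if (!all(model$atoms$atom_name == native$atoms$atom_name))
    stop("model and native atom lists do not correspond")
  P <- coords(model); Q <- coords(native)
  res <- native$atoms$res_index
  n <- nrow(Q)
  pi <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  pj <- sequence((n - 1L):1L) + pi
  keep <- res[pi] != res[pj]
  pi <- pi[keep]; pj <- pj[keep]
  dn <- sqrt(rowSums((Q[pi, , drop = FALSE] - Q[pj, , drop = FALSE])^2))
  sel <- dn < radius
  if (!any(sel)) stop("no qualifying atom pairs within the inclusion radius")
  pi <- pi[sel]; pj <- pj[sel]; dn <- dn[sel]
  dm <- sqrt(rowSums((P[pi, , drop = FALSE] - P[pj, , drop = FALSE])^2))
  dev <- abs(dm - dn)
  mean(vapply(thresholds, function(t) mean(dev < t), numeric(1)))
}

#' Calpha RMSD after optimal superposition
#' @param model,native corresponded `hddr_structure` objects.
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(model, native) {
  superpose_rmsd(coords(model, "CA"), coords(native, "CA"))$rmsd
}

#' Score a decoy set against the native structure
#'
#' Computes GDT-HA, lDDT and Calpha RMSD per decoy plus their arithmetic
#' means (the decoy-averaged overall quality score).
#'
#' @param decoys list of `hddr_structure` decoys.
#' @param native the native `hddr_structure`.
#' @param n_failed number of failed decoys to record.
#' @return an `hddr_quality_report`: list with `per_decoy` (data.frame)
#'   and `average` (named numeric).
#' @export
quality_report <- function(decoys, native, n_failed = 0L) {
  per <- do.call(rbind, lapply(seq_along(decoys), function(k) {
    d <- decoys[[k]]
    data.frame(decoy = k, gdt_ha = gdt_ha(d, native), lddt = lddt(d, native),
               ca_rmsd = ca_rmsd(d, native))
  }))
  structure(list(per_decoy = per,
                 average = c(gdt_ha = mean(per$gdt_ha),
                             lddt = mean(per$lddt),
                             ca_rmsd = mean(per$ca_rmsd)),
                 n_failed = n_failed),
            class = "hddr_quality_report")
}

#' @export
print.hddr_quality_report <- function(x, ...) {
  cat(sprintf("<hddr_quality_report: %d decoys (%d failed)> GDT-HA %.4f, lDDT %.4f, CA-RMSD %.2f A\n",
              nrow(x$per_decoy), x$n_failed, x$average["gdt_ha"],
              x$average["lddt"], x$average["ca_rmsd"]))
  invisible(x)
}
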