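## Simulating |delta d_n| estimators of controlled accuracy.
##
## Signed native-template distance differences are perturbed with additive
## Laplace noise, p_i = |delta_i + eps_i|. A sweep over 5000 Laplace scale
## values b (linear from 0.005*m_obs to 25*m_obs) selects the trial whose
## Pearson correlation between p and the unperturbed |delta| list is
## closest to the requested PCC_SEL; the selected list is then rescaled so
## its mean equals m_pt = PCC_SEL*m_obs + (1 - PCC_SEL)*m_grp, which keeps
## strongly perturbed lists from inflating the average sigma of a model.

#' Perturbation configuration
#'
#' @param pcc_sel target Pearson correlation in [0, 1).
#' @param trials number of Laplace-scale trials (default 5000).
#' @param m_grp group-global mean `|delta d_n|` (Angstrom) used as the
#'   zero-correlation scaling endpoint; defaults to `m_obs` of the list
#'   being perturbed when `NULL`.
#' @param b_range multiples of `m_obs` spanned linearly by the b grid.
#' @param seed integer seed for the noise draws.
#' @return a `hddr_perturbation_config` list.
#' @export
perturbation_config <- function(pcc_sel, trials = 5000L, m_grp = NULL,
                                b_range = c(0.005, 25.0), seed = 1L) {
  stopifnot(pcc_sel >= 0, pcc_sel < 1, trials >= 1L,
            length(b_range) == 2L, b_range[1] < b_range[2])
  structure(list(pcc_sel = pcc_sel, trials = as.integer(trials),
                 m_grp = m_grp, b_range = b_range, seed = as.integer(seed)),
            class = "hddr_perturbation_config")
}

#' Scale a perturbed list to its target mean
#'
#' Multiplies `p` by `m_pt / mean(p)` where
#' `m_pt = pcc_sel * m_obs + (1 - pcc_sel) * m_grp`. At `pcc_sel = 1` the
#' target mean is the mean of the unperturbed list; at `pcc_sel = 0` it is
#' the group-global mean.
#'
#' @param p perturbed values (Angstrom, non-negative).
#' @param pcc_sel the requested correlation.
#' @param m_obs mean of the unperturbed `|delta d_n|` list.
#' @param m_grp group-global mean.
#' @return list with `p` (scaled values) and `m_pt`.
#' @export
scale_to_mpt <- function(p, pcc_sel, m_obs, m_grp) {
  mp <- mean(p)
  if (mp <= 0) stop("perturbed list has non-positive mean")
  m_pt <- pcc_sel * m_obs + (1 - pcc_sel) * m_grp
  list(p = p * (m_pt / mp), m_pt = m_pt)
}

#' Perturb signed deltas to a target correlation
#'
#' Runs the b-sweep heuristic: for each of `cfg$trials` Laplace scales b
#' (linear grid over `cfg$b_range * m_obs`), draws errors eps ~
#' Laplace(0, b), forms `p_i = |delta_i + eps_i|`, computes the Pearson
#' correlation between p and `|delta|`, and keeps the trial whose
#' correlation is closest to `cfg$pcc_sel`. The selected list is scaled
#' with [scale_to_mpt()] (scaling leaves the correlation unchanged).
#'
#' @param deltas signed `delta d_n` values (Angstrom), length >= 3.
#' @param cfg a [perturbation_config()].
#' @return list with `p` (scaled perturbed values), `pcc` (achieved
#'   correlation), `b` (selected Laplace scale), `m_pt`, `m_obs`.
#' @export
perturb_to_target_pcc <- function(deltas, cfg) {
  stopifnot(inherits(cfg, "hddr_perturbation_config"))
  n <- length(deltas)
  if (n < 3L) stop("need at least 3 deltas to define a correlation")
  a <- abs(deltas)
  if (stats::sd(a) == 0) stop("constant |delta| list: correlation undefined")
  m_obs <- mean(a)
  m_grp <- cfg$m_grp %||% m_obs
  b_grid <- seq(cfg$b_range[1] * m_obs, cfg$b_range[2] * m_obs,
                length.out = cfg$trials)
  set.seed(cfg$seed)
  ## one row of Laplace noise per trial, scaled by that trial's b
  E <- matrix(rlaplace(cfg$trials * n, 0, 1), nrow = cfg$trials)
  P <- abs(matrix(deltas, cfg$trials, n, byrow = TRUE) + E * b_grid)
  pccs <- row_pcc(P, a)
  dev <- abs(pccs - cfg$pcc_sel)
  dev[is.na(dev)] <- Inf
  best <- which.min(dev)
  sc <- scale_to_mpt(P[best, ], cfg$pcc_sel, m_obs, m_grp)
  list(p = sc$p, pcc = pccs[best], b = b_grid[best],
       m_pt = sc$m_pt, m_obs = m_obs)
}

#' Model-level perturbation correlation (PCC_MODEL)
#'
#' Averages, over perturbed sets r = 1..n_R and templates u = 1..U, the
#' Pearson correlation between the original `|delta d_n|` list of template
#' u and its perturbed counterpart in set r.
#'
#' @param original list of U numeric vectors (per-template `|delta d_n|`).
#' @param perturbed_sets list of n_R elements, each a list of U numeric
#'   vectors shaped like `original`.
#' @return scalar PCC_MODEL.
#' @export
pcc_model <- function(original, perturbed_sets) {
  if (!is.list(original)) original <- list(original)
  U <- length(original)
  vals <- vapply(perturbed_sets, function(set) {
    if (!is.list(set)) set <- list(set)
    if (length(set) != U) stop("perturbed set has ", length(set),
                               " templates, expected ", U)
    mean(vapply(seq_len(U), function(u) {
      if (length(set[[u]]) != length(original[[u]]))
        stop("length mismatch for template ", u)
      if (length(original[[u]]) < 3L) stop("lists must have length >= 3")
      stats::cor(original[[u]], set[[u]])
    }, numeric(1)))
  }, numeric(1))
  mean(vals)
}

#' Perturb the optimal sigmas of a restraint set
#'
#' Applies [perturb_to_target_pcc()] independently to each HDDR group and
#' each template of a restraint set whose entries carry signed
#' native-template differences (i.e. after [set_optimal_sigma()]). The
#' perturbed values replace the entry sigmas (floored at `floor`); OL
#' weights are recomputed on the perturbed sigmas.
#'
#' @param rs a `hddr_restraint_set` with `d_n` and `d_t` columns.
#' @param pcc_sel target correlation.
#' @param m_grp named per-group global means (Angstrom); groups absent
#'   from the vector fall back to the group's own `m_obs`.
#' @param seed integer seed.
#' @param trials b-sweep trials per group (default 5000).
#' @param floor sigma floor (Angstrom).
#' @return list with `rs` (updated set) and `achieved` data.frame of
#'   per-group/template achieved PCCs.
#' @export
perturb_restraint_sigmas <- function(rs, pcc_sel, m_grp = NULL, seed = 1L,
                                     trials = 5000L, floor = SIGMA_FLOOR) {
  e <- rs$entries
  if (is.null(e$d_n)) stop("restraint set lacks native distances; ",
                           "run set_optimal_sigma() first")
  achieved <- list()
  for (grp in unique(e$group)) {
    for (u in unique(e$u[e$group == grp])) {
      rows <- which(e$group == grp & e$u == u)
      if (length(rows) < 3L) next
      deltas <- e$d_n[rows] - e$d_t[rows]
      if (stats::sd(abs(deltas)) == 0) next
      mg <- if (!is.null(m_grp) && grp %in% names(m_grp)) m_grp[[grp]] else NULL
      cfg <- perturbation_config(pcc_sel, trials = trials, m_grp = mg,
                                 seed = derive_seed(seed, u * 131L + match(grp, HDDR_GROUPS)))
      res <- perturb_to_target_pcc(deltas, cfg)
      e$sigma[rows] <- pmax(res$p, floor)
      achieved[[length(achieved) + 1L]] <-
        data.frame(group = grp, u = u, pcc = res$pcc, b = res$b,
                   m_pt = res$m_pt)
    }
  }
  rs$entries <- e
  rs <- set_weights(rs, "only_lowest")
  list(rs = rs, achieved = do.call(rbind, achieved))
}
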