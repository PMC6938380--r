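## Desk-scale computational experiments on a synthetic corpus: the
## sigma-strategy comparison, the PCC_SEL perturbation sweep, and the
## statistical-potential weight sweep. Magnitudes reported on PDB-derived
## benchmarks are set-specific; only orderings and monotone trends are
## meaningful at this scale.

#' Experiment configuration
#'
#' @param manifest corpus manifest data.frame (from [generate_corpus()])
#'   or the path of a manifest TSV.
#' @param strategy sigma strategy: `"uniform"` (one sigma everywhere),
#'   `"optimal"` (floored `|delta d_n|` + OL weights), `"optimal_u"`
#'   (optimal sigmas, uniform weights), `"optimal_st"` (optimal sigmas,
#'   best single template only), `"baseline"` (seeded random sigmas drawn
#'   with the group-mean of the optimal values preserved) or
#'   `"perturbed"` (Laplace-perturbed optimal sigmas at `pcc_sel`).
#' @param sigma uniform sigma value (A) for `strategy = "uniform"`.
#' @param pcc_sel target correlation for `strategy = "perturbed"`.
#' @param n_sets perturbed sets per target (paper-scale 5).
#' @param trials b-sweep trials per group (paper-scale 5000).
#' @param decoys decoys per condition (paper-scale 16, or 8 per perturbed
#'   set).
#' @param wsp statistical-potential weight; 0 disables F_SP.
#' @param sp a `hddr_spline_potential` (defaults to [toy_potential()]
#'   when `wsp > 0`).
#' @param protocol an [optimization_protocol()].
#' @param seed integer master seed.
#' @return a `hddr_experiment_config` list.
#' @export
experiment_config <- function(manifest,
                              strategy = c("uniform", "optimal", "optimal_u",
                                           "optimal_st", "baseline",
                                           "perturbed"),
                              sigma = 1.0, pcc_sel = 0.0, n_sets = 1L,
                              trials = 5000L, decoys = 2L, wsp = 0,
                              sp = NULL,
                              protocol = optimization_protocol("very_fast"),
                              seed = 1L) {
  strategy <- match.arg(strategy)
  if (is.character(manifest))
    manifest <- utils::read.table(manifest, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  if (wsp > 0 && is.null(sp)) sp <- toy_potential()
  structure(list(manifest = manifest, strategy = strategy, sigma = sigma,
                 pcc_sel = pcc_sel, n_sets = as.integer(n_sets),
                 trials = as.integer(trials), decoys = as.integer(decoys),
                 wsp = wsp, sp = sp, protocol = protocol,
                 seed = as.integer(seed)),
            class = "hddr_experiment_config")
}

## load one corpus target from its manifest row
load_target <- function(row) {
  native <- parse_structure(row$native_pdb)
  templates <- lapply(strsplit(row$template_pdbs, ",")[[1]], parse_structure)
  aln <- parse_alignment(row$alignment, format = "pir")
  list(native = native, templates = templates, aln = aln)
}

## restrict a joined alignment (and template list) to one template
subset_to_template <- function(aln, templates, u) {
  list(aln = new_joined_alignment(aln$target_id, aln$alignments[u]),
       templates = templates[u])
}

## apply a sigma strategy; returns list(rs, pcc_model or NA)
apply_strategy <- function(cfg, rs, native, seed) {
  pccm <- NA_real_
  rs <- switch(cfg$strategy,
    uniform = set_uniform_sigma(rs, cfg$sigma),
    optimal = set_optimal_sigma(rs, native),
    optimal_u = set_weights(set_optimal_sigma(rs, native), "uniform"),
    optimal_st = set_optimal_sigma(rs, native),
    baseline = {
      rs2 <- set_optimal_sigma(rs, native)
      e <- rs2$entries
      set.seed(derive_seed(seed, 33L))
      for (grp in unique(e$group)) {
        rows <- which(e$group == grp)
        m <- mean(e$sigma[rows])
        e$sigma[rows] <- pmax(stats::rexp(length(rows), 1 / m), SIGMA_FLOOR)
      }
      rs2$entries <- e
      set_weights(rs2, "only_lowest")
    },
    perturbed = {
      rs2 <- set_optimal_sigma(rs, native)
      e0 <- rs2$entries
      orig <- lapply(split(seq_len(nrow(e0)), paste(e0$group, e0$u)),
                     function(ix) e0$abs_ddn[ix])
      perturbed <- list(); out_rs <- rs2
      for (r in seq_len(cfg$n_sets)) {
        pr <- perturb_restraint_sigmas(rs2, cfg$pcc_sel,
                                       seed = derive_seed(seed, 500L + r),
                                       trials = cfg$trials)
        e1 <- pr$rs$entries
        perturbed[[r]] <- lapply(split(seq_len(nrow(e1)),
                                       paste(e1$group, e1$u)),
                                 function(ix) e1$sigma[ix])
        out_rs <- pr$rs  # decoys of set r use set r's sigmas (round-robin below)
      }
      ## PCC_MODEL over sets and groups/templates with defined correlations
      vals <- unlist(lapply(perturbed, function(set)
        vapply(names(orig), function(k) {
          if (length(orig[[k]]) >= 3L && stats::sd(orig[[k]]) > 0)
            stats::cor(orig[[k]], set[[k]]) else NA_real_
        }, numeric(1))))
      pccm <- mean(vals, na.rm = TRUE)
      attr(out_rs, "perturbed_sets") <- perturbed
      out_rs
    })
  list(rs = rs, pcc_model = pccm)
}

#' Run one experiment condition over a corpus
#'
#' For every manifest target: loads structures and alignment, builds
#' HDDRs, applies the configured sigma strategy, builds `cfg$decoys`
#' decoys (times `cfg$n_sets` for the perturbed strategy, mirroring the
#' sets-times-decoys protocol) and scores them against the native. Fully
#' seeded; per-target failures are recorded and skipped.
#'
#' @param cfg an [experiment_config()].
#' @param out optional TSV path for the results table.
#' @return data.frame with one row per target: decoy-averaged GDT-HA,
#'   lDDT, Calpha RMSD, PCC_MODEL (where applicable) and failure counts.
#' @export
run_experiment <- function(cfg, out = NULL) {
  stopifnot(inherits(cfg, "hddr_experiment_config"))
  rows <- list()
  for (k in seq_len(nrow(cfg$manifest))) {
    row <- cfg$manifest[k, ]
    res <- tryCatch({
      tgt <- load_target(row)
      aln <- tgt$aln; templates <- tgt$templates
      if (cfg$strategy == "optimal_st") {
        div <- as.numeric(strsplit(as.character(row$realized_divergence),
                                   ",")[[1]])
        best <- which.min(div)
        sub <- subset_to_template(aln, templates, best)
        aln <- sub$aln; templates <- sub$templates
      }
      rs <- build_hddrs(aln, templates, tgt$native)
      st <- apply_strategy(cfg, rs, tgt$native, derive_seed(cfg$seed, k))
      n_sets_eff <- if (cfg$strategy == "perturbed") cfg$n_sets else 1L
      decoys <- list(); failed <- 0L
      for (r in seq_len(n_sets_eff)) {
        rs_r <- if (cfg$strategy == "perturbed" && n_sets_eff > 1L) {
          pr <- perturb_restraint_sigmas(
            set_optimal_sigma(rs, tgt$native), cfg$pcc_sel,
            seed = derive_seed(cfg$seed, k * 1000L + 500L + r),
            trials = cfg$trials)
          pr$rs
        } else st$rs
        dk <- generate_decoys(aln, templates, tgt$native, rs_r,
                              sp = cfg$sp, w_sp = cfg$wsp,
                              protocol = cfg$protocol,
                              n_decoys = cfg$decoys,
                              base_seed = derive_seed(cfg$seed,
                                                      k * 100L + r))
        decoys <- c(decoys, dk$decoys); failed <- failed + dk$failed
      }
      qr <- quality_report(decoys, tgt$native, n_failed = failed)
      data.frame(target = row$target, strategy = cfg$strategy,
                 sigma = cfg$sigma, pcc_sel = cfg$pcc_sel, wsp = cfg$wsp,
                 n_decoys = nrow(qr$per_decoy), n_failed = failed,
                 gdt_ha = qr$average["gdt_ha"], lddt = qr$average["lddt"],
                 ca_rmsd = qr$average["ca_rmsd"],
                 pcc_model = st$pcc_model, row.names = NULL)
    }, error = function(e) {
      warning("target ", row$target, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("all targets failed")
  results <- do.call(rbind, rows)
  if (!is.null(out))
    utils::write.table(results, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  results
}

#' Paired Wilcoxon comparison of two experiment result tables
#'
#' @param a,b result tables from [run_experiment()] sharing targets.
#' @param metric column to compare (default `"gdt_ha"`).
#' @return list with per-table means, mean difference (a - b) and the
#'   paired Wilcoxon signed-rank p-value.
#' @export
compare_conditions <- function(a, b, metric = "gdt_ha") {
  common <- intersect(a$target, b$target)
  va <- a[[metric]][match(common, a$target)]
  vb <- b[[metric]][match(common, b$target)]
  p <- tryCatch(stats::wilcox.test(va, vb, paired = TRUE,
                                   exact = FALSE)$p.value,
                error = function(e) NA_real_)
  list(mean_a = mean(va), mean_b = mean(vb), mean_diff = mean(va - vb),
       n = length(common), p_value = p)
}
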