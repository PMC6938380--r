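## Model building: template-based initialization, conjugate-gradient
## minimization, Metropolis simulated annealing, and multi-decoy runs.
##
## The annealing stage replaces a molecular-dynamics run at desk scale:
## seeded Metropolis moves on Cartesian coordinates let the model escape
## local minima of the composite objective before a final gradient quench.
## The "very_fast" and "slow" protocols mirror a short and a roughly
## 3.4x longer refinement schedule.

#' Optimization protocol
#'
#' @param name `"very_fast"` (3 annealing stages) or `"slow"` (10 stages,
#'   >= 3x the steps).
#' @param cg_iter conjugate-gradient iterations per minimization phase.
#' @param schedule list of `c(temperature, steps)` pairs; overrides the
#'   named default. Temperatures must end low (the final quench is pure
#'   minimization).
#' @param ceiling objective ceiling; models whose F_TOT exceeds it abort.
#'   `NULL` selects `max(1e6, 1e4 * n_restraints)`.
#' @return an `hddr_protocol` list.
#' @export
optimization_protocol <- function(name = c("very_fast", "slow"),
                                  cg_iter = NULL, schedule = NULL,
                                  ceiling = NULL) {
  name <- match.arg(name)
  if (is.null(cg_iter)) cg_iter <- if (name == "very_fast") 150L else 300L
  if (is.null(schedule)) {
    schedule <- if (name == "very_fast") {
      list(c(2.0, 30), c(1.0, 30), c(0.3, 30))
    } else {
      lapply(seq(3.0, 0.1, length.out = 10), function(t) c(t, 35))
    }
  }
  structure(list(name = name, cg_iter = as.integer(cg_iter),
                 schedule = schedule, ceiling = ceiling),
            class = "hddr_protocol")
}

#' Initialize a model from its templates
#'
#' Copies coordinates from the highest-coverage template for aligned
#' residues (atom-by-atom by name; atoms absent from the template residue
#' are placed at their ideal local offset from the Calpha). Unaligned
#' residues keep ideal-geometry coordinates, rigidly shifted to connect
#' to the neighbouring placed residue. A small seeded uniform jitter
#' (default 0.1 A per coordinate) makes decoys start from distinct points.
#'
#' @param aln a `hddr_joined_alignment`.
#' @param templates list of `hddr_structure`.
#' @param topology target `hddr_structure` giving the atom set and
#'   ideal-geometry fallback coordinates.
#' @param seed integer seed.
#' @param jitter half-width of the uniform per-coordinate jitter (A).
#' @return a `hddr_structure` (the initial model).
#' @export
initialize_model <- function(aln, templates, topology, seed = 1L,
                             jitter = 0.1) {
  tmpl_ids <- vapply(aln$alignments, function(a) a$template_id, character(1))
  have <- vapply(templates, function(s) s$id, character(1))
  templates <- templates[match(tmpl_ids, have)]
  corrs <- lapply(seq_along(templates), function(u)
    residue_correspondence(aln$alignments[[u]], topology, templates[[u]]))
  cov <- vapply(corrs, nrow, integer(1))
  if (all(cov == 0)) stop("no aligned residues in any template")
  u <- which.max(cov)
  tmpl <- templates[[u]]
  corr <- corrs[[u]]

  a <- topology$atoms
  X <- coords(topology)
  ta <- tmpl$atoms
  Tx <- coords(tmpl)
  key_t <- paste(ta$res_index, ta$atom_name)
  placed_res <- logical(n_residues(topology))
  for (k in seq_len(nrow(corr))) {
    tr <- corr$target_res[k]; pr <- corr$template_res[k]
    rows <- which(a$res_index == tr)
    tca <- match(paste(pr, "CA"), key_t)
    mca <- rows[a$atom_name[rows] == "CA"]
    for (r in rows) {
      hit <- match(paste(pr, a$atom_name[r]), key_t)
      X[r, ] <- if (!is.na(hit)) Tx[hit, ] else
        Tx[tca, ] + (coords(topology)[r, ] - coords(topology)[mca, ])
    }
    placed_res[tr] <- TRUE
  }
  ## shift unaligned runs so they connect to their aligned neighbours
  nres <- length(placed_res)
  runs <- rle(placed_res)
  pos <- cumsum(c(1L, runs$lengths))
  for (q in seq_along(runs$values)) {
    if (runs$values[q]) next
    s <- pos[q]; e <- pos[q] + runs$lengths[q] - 1L
    rows <- which(a$res_index >= s & a$res_index <= e)
    if (s > 1L) {
      prevC <- which(a$res_index == s - 1L & a$atom_name == "C")
      thisN <- which(a$res_index == s & a$atom_name == "N")
      prevCA <- which(a$res_index == s - 1L & a$atom_name == "CA")
      dir <- X[prevC, ] - X[prevCA, ]
      dir <- dir / max(vnorm(dir), 1e-9)
      target_pos <- X[prevC, ] + IDEAL_BONDS[["C-N"]] * dir
      shift <- target_pos - X[thisN, ]
    } else {
      nextN <- which(a$res_index == e + 1L & a$atom_name == "N")
      thisC <- which(a$res_index == e & a$atom_name == "C")
      target_pos <- X[nextN, ] - c(IDEAL_BONDS[["C-N"]], 0, 0)
      shift <- target_pos - X[thisC, ]
    }
    X[rows, ] <- sweep(X[rows, , drop = FALSE], 2, shift, `+`)
  }
  set.seed(seed)
  X <- X + matrix(stats::runif(length(X), -jitter, jitter), nrow(X), 3)
  model <- set_coords(topology, X)
  model$id <- paste0(aln$target_id, "_model")
  model
}

check_ceiling <- function(f_tot, ceiling) {
  if (!is.finite(f_tot) || f_tot > ceiling)
    stop_hddr(sprintf(
      "objective ceiling exceeded: F_TOT = %.6g > %.6g; model building stopped",
      f_tot, ceiling), "hddr_objective_ceiling_error")
}

#' Minimize the composite objective of a model
#'
#' Runs conjugate gradients to convergence, the protocol's Metropolis
#' annealing schedule, and a final conjugate-gradient quench. Aborts with
#' an `hddr_objective_ceiling_error` whenever F_TOT exceeds the protocol
#' ceiling. The returned model never has a higher F_TOT than the input.
#'
#' @param model initial `hddr_structure`.
#' @param restraints a `hddr_restraint_set` or NULL.
#' @param sp optional `hddr_spline_potential`.
#' @param w_sp statistical-potential weight.
#' @param protocol an [optimization_protocol()].
#' @param seed integer seed for the annealing moves.
#' @param params see [energy_params()].
#' @return list with `model` (optimized structure), `breakdown` (final
#'   [em_energy()] breakdown) and `trace` (data.frame of F_TOT at phase
#'   boundaries).
#' @export
optimize_model <- function(model, restraints = NULL, sp = NULL, w_sp = 0,
                           protocol = optimization_protocol("very_fast"),
                           seed = 1L, params = energy_params()) {
  em <- compile_energy_model(model, restraints, sp, w_sp, params)
  ceiling <- protocol$ceiling %||% max(1e6, 1e4 * max(em$n_restraints, 1L))
  n <- em$n_atoms
  fn <- function(x) em_energy(em, matrix(x, n, 3))$F_TOT
  gr <- function(x) as.vector(em_gradient(em, matrix(x, n, 3)))
  x <- as.vector(coords(model))
  f0 <- fn(x)
  check_ceiling(f0, ceiling)
  trace <- data.frame(phase = "initial", F_TOT = f0)

  cg <- function(x, maxit) {
    res <- stats::optim(x, fn, gr, method = "CG",
                        control = list(maxit = maxit))
    res$par
  }
  x <- cg(x, protocol$cg_iter)
  f_cg <- fn(x)
  check_ceiling(f_cg, ceiling)
  trace <- rbind(trace, data.frame(phase = "cg", F_TOT = f_cg))
  best_x <- x; best_f <- f_cg

  set.seed(seed)
  tmax <- max(vapply(protocol$schedule, `[`, numeric(1), 1), 1e-9)
  f_cur <- f_cg
  for (stage in protocol$schedule) {
    temp <- stage[1]; steps <- stage[2]
    if (temp <= 0) next
    sd_move <- 0.05 + 0.25 * temp / tmax
    for (s in seq_len(steps)) {
      sel <- sample.int(n, max(1L, n %/% 5L))
      prop <- x
      idx <- c(sel, sel + n, sel + 2L * n)
      prop[idx] <- prop[idx] + stats::rnorm(length(idx), 0, sd_move)
      f_prop <- fn(prop)
      if (is.finite(f_prop) &&
          (f_prop <= f_cur || stats::runif(1) < exp(-(f_prop - f_cur) / temp))) {
        x <- prop; f_cur <- f_prop
        if (f_cur < best_f) { best_f <- f_cur; best_x <- x }
      }
    }
    check_ceiling(f_cur, ceiling)
    trace <- rbind(trace,
                   data.frame(phase = sprintf("anneal_T%.2f", temp),
                              F_TOT = f_cur))
  }
  x <- cg(x, protocol$cg_iter)
  f_q <- fn(x)
  if (f_q > best_f) {  # quench from the best visited state instead
    x2 <- cg(best_x, protocol$cg_iter)
    if (fn(x2) < f_q) { x <- x2; f_q <- fn(x) }
  }
  if (f_q > f0) { x <- as.vector(coords(model)); f_q <- f0 }
  check_ceiling(f_q, ceiling)
  trace <- rbind(trace, data.frame(phase = "quench", F_TOT = f_q))
  list(model = set_coords(model, matrix(x, n, 3)),
       breakdown = em_energy(em, matrix(x, n, 3)),
       trace = trace)
}

#' Build a set of decoys
#'
#' Runs [initialize_model()] + [optimize_model()] `n_decoys` times with
#' seeds `base_seed + k`. Decoys aborting on the objective ceiling are
#' recorded as failed; at least one decoy must succeed.
#'
#' @param aln a `hddr_joined_alignment`.
#' @param templates list of `hddr_structure`.
#' @param topology target topology structure.
#' @param restraints a `hddr_restraint_set`.
#' @param sp optional `hddr_spline_potential`.
#' @param w_sp statistical-potential weight.
#' @param protocol an [optimization_protocol()].
#' @param n_decoys number of decoys (paper-scale default 16).
#' @param base_seed integer; decoy k uses seed `base_seed + k`.
#' @param params see [energy_params()].
#' @return list with `decoys` (list of structures), `breakdowns`,
#'   `failed` (number of ceiling aborts).
#' @export
generate_decoys <- function(aln, templates, topology, restraints,
                            sp = NULL, w_sp = 0,
                            protocol = optimization_protocol("very_fast"),
                            n_decoys = 16L, base_seed = 1L,
                            params = energy_params()) {
  stopifnot(n_decoys >= 1L)
  decoys <- list(); breakdowns <- list(); failed <- 0L
  for (k in seq_len(n_decoys)) {
    sk <- base_seed + k
    res <- tryCatch({
      init <- initialize_model(aln, templates, topology, seed = sk)
      optimize_model(init, restraints, sp, w_sp, protocol, seed = sk,
                     params = params)
    }, hddr_objective_ceiling_error = function(e) e)
    if (inherits(res, "hddr_objective_ceiling_error")) {
      failed <- failed + 1L
    } else {
      decoys[[length(decoys) + 1L]] <- res$model
      breakdowns[[length(breakdowns) + 1L]] <- res$breakdown
    }
  }
  if (!length(decoys))
    stop("all ", n_decoys, " decoys failed on the objective ceiling")
  list(decoys = decoys, breakdowns = breakdowns, failed = failed)
}
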