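## Composite objective function F_TOT = F_PHYS + F_HOM + w_SP * F_SP.
##
## F_PHYS is a simplified stereochemistry: harmonic bonds and angles on
## the ideal-geometry constants plus a soft-sphere quadratic repulsion for
## non-bonded atoms (there is deliberately no attractive physical term).
## F_HOM sums the -log mixture densities of the homology-derived distance
## restraints. F_SP sums spline statistical-potential terms over
## non-bonded heavy-atom pairs within the contact shell. All three terms
## have analytic Cartesian gradients for the minimizer.

#' Parameters of the physical (stereochemical) terms
#'
#' @param k_bond harmonic bond force constant (energy / A^2).
#' @param k_angle harmonic angle force constant (energy / rad^2).
#' @param k_rep soft-sphere repulsion constant (energy / A^2).
#' @param ss_rmin soft-sphere contact distance (A); pairs closer than this
#'   are penalized quadratically.
#' @export
energy_params <- function(k_bond = 100, k_angle = 20, k_rep = 10,
                          ss_rmin = 2.8) {
  list(k_bond = k_bond, k_angle = k_angle, k_rep = k_rep, ss_rmin = ss_rmin)
}

## covalent bond list (i, j, r0) for a reduced-atom topology
topology_bonds <- function(s) {
  a <- s$atoms
  key <- paste(a$res_index, a$atom_name)
  at <- function(res, name) match(paste(res, name), key)
  nres <- n_residues(s)
  rows <- list()
  add <- function(i, j, r0) {
    ok <- !is.na(i) & !is.na(j)
    if (any(ok)) rows[[length(rows) + 1L]] <<- cbind(i[ok], j[ok], r0)
  }
  r <- seq_len(nres)
  add(at(r, "N"), at(r, "CA"), IDEAL_BONDS[["N-CA"]])
  add(at(r, "CA"), at(r, "C"), IDEAL_BONDS[["CA-C"]])
  add(at(r, "C"), at(r, "O"), IDEAL_BONDS[["C-O"]])
  add(at(r, "CA"), at(r, "CB"), IDEAL_BONDS[["CA-CB"]])
  add(at(r, "CB"), at(r, "CG"), IDEAL_BONDS[["CB-CG"]])
  if (nres > 1L) add(at(r[-nres], "C"), at(r[-1], "N"), IDEAL_BONDS[["C-N"]])
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(numeric(0), 0, 3)
  colnames(m) <- c("i", "j", "r0")
  m
}

## angle list (a, b, c, theta0 in radians)
topology_angles <- function(s) {
  a <- s$atoms
  key <- paste(a$res_index, a$atom_name)
  at <- function(res, name) match(paste(res, name), key)
  nres <- n_residues(s)
  rows <- list()
  add <- function(i, j, k, th) {
    ok <- !is.na(i) & !is.na(j) & !is.na(k)
    if (any(ok))
      rows[[length(rows) + 1L]] <<- cbind(i[ok], j[ok], k[ok], th * pi / 180)
  }
  r <- seq_len(nres)
  add(at(r, "N"), at(r, "CA"), at(r, "C"), IDEAL_ANGLES_DEG[["N-CA-C"]])
  add(at(r, "CA"), at(r, "C"), at(r, "O"), IDEAL_ANGLES_DEG[["CA-C-O"]])
  add(at(r, "N"), at(r, "CA"), at(r, "CB"), IDEAL_ANGLES_DEG[["N-CA-CB"]])
  add(at(r, "CA"), at(r, "CB"), at(r, "CG"), IDEAL_ANGLES_DEG[["CA-CB-CG"]])
  if (nres > 1L) {
    add(at(r[-nres], "CA"), at(r[-nres], "C"), at(r[-1], "N"),
        IDEAL_ANGLES_DEG[["CA-C-N"]])
    add(at(r[-nres], "C"), at(r[-1], "N"), at(r[-1], "CA"),
        IDEAL_ANGLES_DEG[["C-N-CA"]])
  }
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(numeric(0), 0, 4)
  colnames(m) <- c("a", "b", "c", "theta0")
  m
}

## non-bonded pairs: graph distance > 2 covalent bonds, i < j
nonbonded_pairs <- function(n_atoms, bonds) {
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  excl <- vector("list", n_atoms)  # atoms within 2 bonds of i (incl. i)
  for (i in seq_len(n_atoms)) {
    n1 <- adj[[i]]
    n2 <- unique(unlist(adj[n1], use.names = FALSE))
    excl[[i]] <- unique(c(i, n1, n2))
  }
  pi <- rep.int(seq_len(n_atoms - 1L), (n_atoms - 1L):1L)
  pj <- sequence((n_atoms - 1L):1L) + pi
  keep <- !mapply(function(i, j) j %in% excl[[i]], pi, pj)
  cbind(i = pi[keep], j = pj[keep])
}

## resolve restraint atom references against an arbitrary structure
resolve_restraint_atoms <- function(rs, model) {
  e <- rs$entries
  a <- model$atoms
  key <- paste(a$res_index, a$atom_name)
  ai <- match(paste(e$res_i, e$atom_i), key)
  aj <- match(paste(e$res_j, e$atom_j), key)
  if (anyNA(ai) || anyNA(aj)) {
    bad <- which(is.na(ai) | is.na(aj))[1]
    stop("restrained atom missing from model: residue ", e$res_i[bad], " ",
         e$atom_i[bad], " / residue ", e$res_j[bad], " ", e$atom_j[bad])
  }
  rs$entries$ai <- ai
  rs$entries$aj <- aj
  rs
}

#' Compile an energy model for fast repeated evaluation
#'
#' Precomputes bond/angle lists, the non-bonded pair list (atoms more than
#' two covalent bonds apart), restraint entry arrays and statistical-
#' potential term assignments for a fixed topology, so the objective and
#' its gradient can be evaluated many times during minimization.
#'
#' @param model a `hddr_structure` (topology; coordinates may change).
#' @param restraints a `hddr_restraint_set` or NULL.
#' @param sp a `hddr_spline_potential` or NULL.
#' @param w_sp weight of the statistical-potential term (>= 0).
#' @param params see [energy_params()].
#' @return an object of class `hddr_energy_model`.
#' @export
compile_energy_model <- function(model, restraints = NULL, sp = NULL,
                                 w_sp = 0, params = energy_params()) {
  stopifnot(w_sp >= 0)
  n <- nrow(model$atoms)
  bonds <- topology_bonds(model)
  angles <- topology_angles(model)
  nb <- nonbonded_pairs(n, bonds)
  em <- list(n_atoms = n, bonds = bonds, angles = angles, nb = nb,
             params = params, w_sp = w_sp, sp = sp)
  if (!is.null(restraints) && nrow(restraints$entries)) {
    rs <- resolve_restraint_atoms(restraints, model)
    e <- rs$entries[rs$entries$w > 0, , drop = FALSE]
    rid_f <- factor(e$rid)
    ridx <- as.integer(rid_f)
    pairs <- !duplicated(ridx)
    em$r_entries <- list(
      ridx = ridx, d_t = e$d_t, sigma = e$sigma, w = e$w,
      n_rid = nlevels(rid_f),
      pi = e$ai[pairs][order(ridx[pairs])],
      pj = e$aj[pairs][order(ridx[pairs])])
    grp <- split(seq_along(ridx), ridx)
    em$r_entries$multi <- grp[lengths(grp) > 1L]
    em$r_entries$single <- which(ridx %in% as.integer(names(grp[lengths(grp) == 1L])))
    em$n_restraints <- n_restraints(restraints)
  } else {
    em$n_restraints <- 0L
  }
  if (!is.null(sp)) {
    ty <- sp_atom_type(model$atoms$atom_name)
    keys <- sp_pair_key(ty[nb[, "i"]], ty[nb[, "j"]])
    miss <- setdiff(unique(keys), names(sp$terms))
    if (length(miss))
      stop("unknown atom-type pair(s) in potential: ",
           paste(miss, collapse = ", "))
    em$sp_tidx <- match(keys, names(sp$terms))
  }
  class(em) <- "hddr_energy_model"
  em
}

## accumulate per-pair gradient contributions into an n x 3 matrix
acc_pairs <- function(G, idx_i, idx_j, gmat) {
  for (side in 1:2) {
    idx <- if (side == 1) idx_i else idx_j
    s <- if (side == 1) 1 else -1
    acc <- rowsum(s * gmat, group = idx)
    rows <- as.integer(rownames(acc))
    G[rows, ] <- G[rows, ] + acc
  }
  G
}

## physical term: returns list(E, G or NULL)
phys_term <- function(em, X, grad = FALSE) {
  p <- em$params
  G <- if (grad) matrix(0, em$n_atoms, 3) else NULL
  E <- 0
  b <- em$bonds
  if (nrow(b)) {
    dxyz <- X[b[, "i"], , drop = FALSE] - X[b[, "j"], , drop = FALSE]
    d <- sqrt(rowSums(dxyz^2))
    E <- E + sum(p$k_bond * (d - b[, "r0"])^2)
    if (grad) {
      gmag <- 2 * p$k_bond * (d - b[, "r0"]) / pmax(d, 1e-12)
      G <- acc_pairs(G, b[, "i"], b[, "j"], gmag * dxyz)
    }
  }
  an <- em$angles
  if (!is.null(an) && nrow(an)) {
    u <- X[an[, "a"], , drop = FALSE] - X[an[, "b"], , drop = FALSE]
    v <- X[an[, "c"], , drop = FALSE] - X[an[, "b"], , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    cosang <- rowSums(u * v) / (nu * nv)
    cosang <- pmin(1 - 1e-12, pmax(-1 + 1e-12, cosang))
    th <- acos(cosang)
    E <- E + sum(p$k_angle * (th - an[, "theta0"])^2)
    if (grad) {
      sinth <- pmax(sqrt(1 - cosang^2), 1e-8)
      pref <- 2 * p$k_angle * (th - an[, "theta0"]) * (-1 / sinth)
      ga <- pref * (v / (nu * nv) - cosang * u / nu^2)
      gc <- pref * (u / (nu * nv) - cosang * v / nv^2)
      acc <- rowsum(rbind(ga, gc, -(ga + gc)),
                    group = c(an[, "a"], an[, "c"], an[, "b"]))
      rows <- as.integer(rownames(acc))
      G[rows, ] <- G[rows, ] + acc
    }
  }
  nb <- em$nb
  if (nrow(nb)) {
    dxyz <- X[nb[, "i"], , drop = FALSE] - X[nb[, "j"], , drop = FALSE]
    d <- sqrt(rowSums(dxyz^2))
    sel <- which(d < p$ss_rmin)
    if (length(sel)) {
      dd <- d[sel]
      E <- E + sum(p$k_rep * (p$ss_rmin - dd)^2)
      if (grad) {
        gmag <- -2 * p$k_rep * (p$ss_rmin - dd) / pmax(dd, 1e-12)
        G <- acc_pairs(G, nb[sel, "i"], nb[sel, "j"],
                       gmag * dxyz[sel, , drop = FALSE])
      }
    }
  }
  list(E = E, G = G)
}

## homology restraint term
hom_term <- function(em, X, grad = FALSE) {
  re <- em$r_entries
  if (is.null(re))
    return(list(E = 0, G = if (grad) matrix(0, em$n_atoms, 3) else NULL))
  dxyz <- X[re$pi, , drop = FALSE] - X[re$pj, , drop = FALSE]
  d_m <- sqrt(rowSums(dxyz^2))        # one per restraint (rid order)
  dm_e <- d_m[re$ridx]                # one per entry
  le <- log(re$w) - log(re$sigma) - 0.5 * log(2 * pi) -
    (dm_e - re$d_t)^2 / (2 * re$sigma^2)
  logf <- numeric(re$n_rid)
  logf[re$ridx[re$single]] <- le[re$single]
  for (ix in re$multi) {
    m <- max(le[ix])
    logf[re$ridx[ix[1]]] <- m + log(sum(exp(le[ix] - m)))
  }
  E <- -sum(logf)
  G <- NULL
  if (grad) {
    sm <- exp(le - logf[re$ridx])     # softmax responsibilities per entry
    dF_ddm_e <- sm * (dm_e - re$d_t) / re$sigma^2
    dF_ddm <- as.numeric(rowsum(dF_ddm_e, group = re$ridx))
    gmag <- dF_ddm / pmax(d_m, 1e-12)
    G <- acc_pairs(matrix(0, em$n_atoms, 3), re$pi, re$pj, gmag * dxyz)
  }
  list(E = E, G = G)
}

## statistical potential term
sp_term <- function(em, X, grad = FALSE) {
  G <- if (grad) matrix(0, em$n_atoms, 3) else NULL
  if (is.null(em$sp) || !nrow(em$nb)) return(list(E = 0, G = G))
  nb <- em$nb
  dxyz <- X[nb[, "i"], , drop = FALSE] - X[nb[, "j"], , drop = FALSE]
  d <- sqrt(rowSums(dxyz^2))
  inshell <- which(d <= em$sp$cutoff)
  E <- 0
  if (length(inshell)) {
    tidx <- em$sp_tidx[inshell]
    for (t in unique(tidx)) {
      sel <- inshell[tidx == t]
      fn <- em$sp$terms[[t]]$fun
      E <- E + sum(fn(d[sel]))
      if (grad) {
        gmag <- fn(d[sel], deriv = 1) / pmax(d[sel], 1e-12)
        G <- acc_pairs(G, nb[sel, "i"], nb[sel, "j"],
                       gmag * dxyz[sel, , drop = FALSE])
      }
    }
  }
  list(E = E, G = G)
}

#' Evaluate one objective term and (optionally) its gradient
#'
#' @param em a compiled `hddr_energy_model`.
#' @param X coordinate matrix (n_atoms x 3).
#' @param term one of `"phys"`, `"hom"`, `"sp"`.
#' @param grad whether to compute the analytic gradient.
#' @return list with `E` (scalar) and `G` (n x 3 matrix or NULL).
#' @export
em_term <- function(em, X, term = c("phys", "hom", "sp"), grad = FALSE) {
  switch(match.arg(term),
         phys = phys_term(em, X, grad),
         hom = hom_term(em, X, grad),
         sp = sp_term(em, X, grad))
}

#' Evaluate the full objective breakdown
#'
#' @param em a compiled `hddr_energy_model`.
#' @param X coordinate matrix (n_atoms x 3).
#' @return an `hddr_objective_breakdown`: list with `F_PHYS`, `F_HOM`,
#'   `F_SP`, `w_SP` and `F_TOT = F_PHYS + F_HOM + w_SP * F_SP`.
#' @export
em_energy <- function(em, X) {
  fp <- phys_term(em, X)$E
  fh <- hom_term(em, X)$E
  fs <- sp_term(em, X)$E
  structure(list(F_PHYS = fp, F_HOM = fh, F_SP = fs, w_SP = em$w_sp,
                 F_TOT = fp + fh + em$w_sp * fs),
            class = "hddr_objective_breakdown")
}

#' @export
print.hddr_objective_breakdown <- function(x, ...) {
  cat(sprintf("F_TOT = %.4f (F_PHYS = %.4f, F_HOM = %.4f, F_SP = %.4f, w_SP = %.2f)\n",
              x$F_TOT, x$F_PHYS, x$F_HOM, x$F_SP, x$w_SP))
  invisible(x)
}

#' Analytic gradient of the full objective
#'
#' @param em a compiled `hddr_energy_model`.
#' @param X coordinate matrix (n_atoms x 3).
#' @return n x 3 gradient matrix of `F_TOT`.
#' @export
em_gradient <- function(em, X) {
  G <- phys_term(em, X, grad = TRUE)$G + hom_term(em, X, grad = TRUE)$G
  if (!is.null(em$sp) && em$w_sp > 0)
    G <- G + em$w_sp * sp_term(em, X, grad = TRUE)$G
  G
}

#' Evaluate the composite objective of a model
#'
#' Convenience wrapper: compiles an energy model for `model` and returns
#' the objective breakdown at its current coordinates.
#'
#' @param model a `hddr_structure`.
#' @param restraints a `hddr_restraint_set` or NULL.
#' @param sp a `hddr_spline_potential` or NULL.
#' @param w_sp statistical-potential weight (>= 0).
#' @param params see [energy_params()].
#' @return an `hddr_objective_breakdown`.
#' @export
evaluate_objective <- function(model, restraints = NULL, sp = NULL,
                               w_sp = 0, params = energy_params()) {
  em <- compile_energy_model(model, restraints, sp, w_sp, params)
  em_energy(em, coords(model))
}
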