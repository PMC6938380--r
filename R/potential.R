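## Pairwise statistical potentials as interpolating cubic splines.
##
## Each atom-type pair carries a table of (knot distance, energy) values on
## a uniform grid ending at the contact-shell cutoff (default 8.0 A, past
## which knowledge-based terms are essentially flat). The working form is
## a natural cubic spline through the knots; beyond the cutoff the energy
## is exactly 0. Real DOPE/DFIRE-style tables can be loaded from TSV; a
## built-in smooth toy potential (repulsive core + contact-distance well)
## covers the coarse atom types of the synthetic corpus.

SP_ATOM_TYPES <- c("N", "CA", "C", "O", "SC")

## coarse type of an atom by name
sp_atom_type <- function(atom_name) {
  ifelse(atom_name %in% BACKBONE_ATOMS, atom_name, "SC")
}

sp_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Construct a spline statistical potential
#'
#' @param knot_table data.frame with columns `type_a`, `type_b`, `knot`
#'   (distance, Angstrom) and `energy`. Knots must be strictly increasing
#'   per pair and shared across pairs need not be identical.
#' @param cutoff contact shell (Angstrom); energies are 0 beyond it.
#' @return object of class `hddr_spline_potential`.
#' @export
new_spline_potential <- function(knot_table, cutoff = 8.0) {
  stopifnot(all(c("type_a", "type_b", "knot", "energy") %in% names(knot_table)))
  keys <- sp_pair_key(knot_table$type_a, knot_table$type_b)
  terms <- lapply(split(knot_table, keys), function(d) {
    d <- d[order(d$knot), , drop = FALSE]
    if (any(diff(d$knot) <= 0)) stop("knots must be strictly increasing")
    list(knots = d$knot, energy = d$energy,
         fun = stats::splinefun(d$knot, d$energy, method = "natural"))
  })
  structure(list(terms = terms, cutoff = cutoff),
            class = "hddr_spline_potential")
}

#' Built-in toy statistical potential
#'
#' A smooth well per coarse atom-type pair: quadratic repulsion below the
#' contact distance, a Gaussian well just beyond it, cosine-tapered to 0
#' at the cutoff; tabulated on a 0.25 Angstrom knot grid and spline
#' interpolated. A stand-in for externally supplied knowledge-based
#' tables, not a fit to any database.
#'
#' @param cutoff contact shell (Angstrom).
#' @param spacing knot spacing (Angstrom).
#' @return a `hddr_spline_potential`.
#' @export
toy_potential <- function(cutoff = 8.0, spacing = 0.25) {
  radii <- c(N = 1.5, CA = 1.9, C = 1.8, O = 1.45, SC = 2.1)
  knots <- seq(0.5, cutoff, by = spacing)
  rows <- list()
  tys <- names(radii)
  for (i in seq_along(tys)) for (j in i:length(tys)) {
    s <- radii[[i]] + radii[[j]]
    rmin <- s + 0.4
    e <- 2 * pmax(0, s - knots)^2 - 0.8 * exp(-(knots - rmin)^2 / (2 * 0.8^2))
    taper <- ifelse(knots > cutoff - 1,
                    0.5 * (1 + cos(pi * (knots - (cutoff - 1)))), 1)
    e <- e * taper
    e[length(e)] <- 0
    rows[[length(rows) + 1L]] <- data.frame(
      type_a = tys[i], type_b = tys[j], knot = knots, energy = e)
  }
  new_spline_potential(do.call(rbind, rows), cutoff = cutoff)
}

#' Evaluate a statistical-potential term
#'
#' Natural-cubic-spline interpolation of the pair's knot energies at
#' distance `r`; exactly 0 beyond the cutoff.
#'
#' @param sp a `hddr_spline_potential`.
#' @param type_a,type_b coarse atom types (order-free).
#' @param r distance(s) in Angstrom (> 0).
#' @param deriv 0 for the energy, 1 for its derivative in r.
#' @return energy (or derivative) value(s).
#' @export
spline_pair_energy <- function(sp, type_a, type_b, r, deriv = 0L) {
  if (any(r <= 0)) stop("distance must be positive")
  key <- sp_pair_key(type_a, type_b)
  term <- sp$terms[[key]]
  if (is.null(term))
    stop("unknown atom-type pair: ", key, " (known: ",
         paste(names(sp$terms), collapse = ", "), ")")
  out <- term$fun(r, deriv = deriv)
  out[r > sp$cutoff] <- 0
  out
}

#' Write a spline potential's knot table as TSV
#' @param sp a `hddr_spline_potential`.
#' @param path output path.
#' @export
write_potential <- function(sp, path) {
  rows <- lapply(names(sp$terms), function(k) {
    t <- sp$terms[[k]]
    ty <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(type_a = ty[1], type_b = ty[2], knot = t$knots,
               energy = t$energy)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a spline potential from a TSV knot table
#' @param path TSV with columns type_a, type_b, knot, energy.
#' @param cutoff contact shell (Angstrom).
#' @export
read_potential <- function(path, cutoff = 8.0) {
  new_spline_potential(utils::read.table(path, sep = "\t", header = TRUE,
                                         stringsAsFactors = FALSE),
                       cutoff = cutoff)
}
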