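# Shared fixtures: tiny hand-written PDB/alignment texts and generator
# shortcuts. Everything is built in code at test time.

pdb_two_residues <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.422   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       2.910   1.749   0.773  1.00  0.00           O",
    "ATOM      5  N   GLY A   2       1.463   2.263  -0.872  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       1.899   3.650  -0.974  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       3.325   3.755  -1.503  1.00  0.00           C",
    "ATOM      8  O   GLY A   2       3.598   4.684  -2.263  1.00  0.00           O",
    "END")
}

write_tmp_pdb <- function(lines, name = "fix.pdb") {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

## small canonical single-template pair used across tests
std_pair <- function(seed = 42, length = 20, divergence = 1.5,
                     aln_error = 0.05, n_templates = 1) {
  generate_pair(toy_spec(length = length, fold = "mixed",
                         divergence = divergence, aln_error = aln_error,
                         n_templates = n_templates, seed = seed))
}

## rigid transform helper: random rotation + translation
rigid_transform <- function(X, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(A))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(X %*% R, 2, runif(3, -20, 20), `+`)
}

apply_rigid <- function(s, seed = 1) {
  set_coords(s, rigid_transform(coords(s), seed))
}

## independent natural-cubic-spline oracle (tridiagonal second-derivative
## solve), used to cross-check the spline potential evaluation
natural_spline_oracle <- function(x, y, x0) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  r <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    r[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  m <- solve(A, r)  # second derivatives at knots
  vapply(x0, function(xx) {
    i <- max(1, min(n - 1, findInterval(xx, x)))
    t <- xx - x[i]
    y[i] + t * ((y[i + 1] - y[i]) / h[i] - h[i] * (2 * m[i] + m[i + 1]) / 6) +
      t^2 * m[i] / 2 + t^3 * (m[i + 1] - m[i]) / (6 * h[i])
  }, numeric(1))
}
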