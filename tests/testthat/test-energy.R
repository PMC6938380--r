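two_atom_system <- function(dist = 5) {
  atoms <- data.frame(
    res_index = c(1L, 4L), res_name = "GLY", atom_name = "CA",
    element = "C", x = c(0, dist), y = 0, z = 0)
  new_structure("dimer", atoms)
}

two_atom_restraint <- function(model, d_t = 4, sigma = 1) {
  e <- data.frame(rid = "CA-CA:1:2", group = "CA-CA", ai = 1L, aj = 2L,
                  res_i = 1L, atom_i = "CA", res_j = 2L, atom_j = "CA",
                  u = 1L, template_id = "t", d_t = d_t, sigma = sigma, w = 1)
  structure(list(entries = e, target_id = "dimer", template_ids = "t",
                 cutoffs = default_cutoffs(), min_sep = NULL,
                 similarity = NULL),
            class = "hddr_restraint_set")
}

test_that("a single restraint reproduces the harmonic objective value", {
  m <- two_atom_system(5)
  rs <- two_atom_restraint(m, d_t = 4, sigma = 1)
  b <- evaluate_objective(m, rs)
  expect_equal(b$F_PHYS, 0)            # two distant atoms, no bonds
  expect_equal(b$F_TOT, 1.418939, tolerance = 1e-6)
})

test_that("breakdown satisfies F_TOT = F_PHYS + F_HOM + w_SP * F_SP", {
  pair <- std_pair(seed = 8, length = 14)
  rs <- set_optimal_sigma(build_hddrs(pair$aln, pair$templates, pair$native),
                          pair$native)
  sp <- toy_potential()
  for (w in c(0, 0.5, 1.0)) {
    b <- evaluate_objective(pair$native, rs, sp, w_sp = w)
    expect_lt(abs(b$F_TOT - (b$F_PHYS + b$F_HOM + w * b$F_SP)), 1e-9)
    expect_true(all(is.finite(unlist(b[1:5]))))
  }
  ## w_SP = 0 recovers the two-term objective; doubling w_SP doubles
  ## the F_SP contribution and leaves the other terms unchanged
  b0 <- evaluate_objective(pair$native, rs, sp, w_sp = 0)
  b1 <- evaluate_objective(pair$native, rs, sp, w_sp = 1)
  b2 <- evaluate_objective(pair$native, rs, sp, w_sp = 2)
  expect_equal(b0$F_TOT, b0$F_PHYS + b0$F_HOM)
  expect_equal(b1$F_PHYS, b2$F_PHYS)
  expect_equal(b1$F_HOM, b2$F_HOM)
  expect_equal(b2$F_TOT - b0$F_TOT, 2 * (b1$F_TOT - b0$F_TOT),
               tolerance = 1e-9)
})

test_that("F_HOM is minimized at d_m = d_t with value ln(sigma sqrt(2 pi))", {
  rs <- two_atom_restraint(NULL, d_t = 4, sigma = 0.7)
  grid <- seq(3, 5, by = 1e-3)
  vals <- vapply(grid, function(d)
    evaluate_objective(two_atom_system(d), rs)$F_HOM, numeric(1))
  expect_lte(abs(grid[which.min(vals)] - 4), 1e-3)
  expect_equal(min(vals), log(0.7 * sqrt(2 * pi)), tolerance = 1e-6)
})

test_that("spline terms vanish past the cutoff and pass through knots", {
  sp <- toy_potential()
  expect_identical(spline_pair_energy(sp, "CA", "CA", 9.0), 0)
  expect_identical(spline_pair_energy(sp, "SC", "N", 8.5), 0)
  term <- sp$terms[["CA|CA"]]
  expect_equal(spline_pair_energy(sp, "CA", "CA", term$knots),
               term$energy)
  ## near-zero at the cutoff knot keeps the potential continuous there
  expect_equal(spline_pair_energy(sp, "CA", "CA", 8.0), 0)
  expect_error(spline_pair_energy(sp, "CA", "ZZ", 3), "unknown")
  expect_error(spline_pair_energy(sp, "CA", "CA", -1), "positive")
})

test_that("spline evaluation matches an independent natural-spline oracle", {
  sp <- toy_potential()
  term <- sp$terms[["O|SC"]]
  mids <- head(term$knots, -1) + diff(term$knots) / 2
  oracle <- natural_spline_oracle(term$knots, term$energy, mids)
  expect_equal(spline_pair_energy(sp, "O", "SC", mids), oracle,
               tolerance = 1e-9)
})

test_that("potential TSV round trips", {
  sp <- toy_potential()
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_potential(sp, path)
  sp2 <- read_potential(path)
  r <- seq(1, 8, by = 0.37)
  expect_equal(spline_pair_energy(sp2, "CA", "SC", r),
               spline_pair_energy(sp, "CA", "SC", r), tolerance = 1e-9)
})

test_that("analytic gradients match central differences term by term", {
  pair <- std_pair(seed = 15, length = 10)
  rs <- set_optimal_sigma(build_hddrs(pair$aln, pair$templates, pair$native),
                          pair$native)
  em <- compile_energy_model(pair$native, rs, toy_potential(), w_sp = 0.5)
  set.seed(99)
  h <- 1e-5
  for (rep in 1:3) {
    X <- coords(pair$native) +
      matrix(rnorm(3 * nrow(pair$native$atoms), 0, 0.25), ncol = 3)
    for (tm in c("phys", "hom", "sp")) {
      G <- em_term(em, X, tm, grad = TRUE)$G
      ks <- sample(length(X), 25)
      for (k in ks) {
        Xp <- X; Xp[k] <- Xp[k] + h
        Xm <- X; Xm[k] <- Xm[k] - h
        fd <- (em_term(em, Xp, tm)$E - em_term(em, Xm, tm)$E) / (2 * h)
        expect_equal(G[k], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("F_TOT is invariant under rigid transforms of the model", {
  pair <- std_pair(seed = 16, length = 12)
  rs <- set_optimal_sigma(build_hddrs(pair$aln, pair$templates, pair$native),
                          pair$native)
  sp <- toy_potential()
  b0 <- evaluate_objective(pair$native, rs, sp, w_sp = 0.7)
  for (s in 1:3) {
    bt <- evaluate_objective(apply_rigid(pair$native, seed = s), rs, sp,
                             w_sp = 0.7)
    expect_lt(abs(bt$F_TOT - b0$F_TOT), 1e-8 * max(1, abs(b0$F_TOT)))
  }
})

test_that("restrained atoms missing from the model raise an error", {
  pair <- std_pair(seed = 17, length = 10)
  rs <- build_hddrs(pair$aln, pair$templates, pair$native)
  clipped <- pair$native
  clipped$atoms <- clipped$atoms[clipped$atoms$atom_name != "CG", ]
  expect_error(evaluate_objective(clipped, rs), "missing from model")
})
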