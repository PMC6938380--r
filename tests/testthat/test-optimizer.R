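test_that("a lone harmonic restraint converges to its template distance", {
  atoms <- data.frame(res_index = c(1L, 4L), res_name = "GLY",
                      atom_name = "CA", element = "C",
                      x = c(0, 6.5), y = 0, z = 0)
  m <- new_structure("dimer", atoms)
  e <- data.frame(rid = "CA-CA:1:2", group = "CA-CA", ai = 1L, aj = 2L,
                  res_i = 1L, atom_i = "CA", res_j = 2L, atom_j = "CA",
                  u = 1L, template_id = "t", d_t = 4, sigma = 1, w = 1)
  rs <- structure(list(entries = e, target_id = "dimer",
                       template_ids = "t", cutoffs = default_cutoffs(),
                       min_sep = NULL, similarity = NULL),
                  class = "hddr_restraint_set")
  res <- optimize_model(m, rs, seed = 1)
  X <- coords(res$model)
  expect_equal(sqrt(sum((X[1, ] - X[2, ])^2)), 4, tolerance = 1e-3)
  expect_lte(res$trace$F_TOT[nrow(res$trace)], res$trace$F_TOT[1])
})

test_that("initialization copies the template and jitters decoy starts", {
  pair <- std_pair(seed = 19, length = 12, aln_error = 0)
  m1 <- initialize_model(pair$aln, pair$templates, pair$native, seed = 1)
  m2 <- initialize_model(pair$aln, pair$templates, pair$native, seed = 2)
  ## identity alignment: initial model is the template plus small jitter
  expect_lt(max(abs(coords(m1) - coords(pair$templates[[1]]))), 0.5)
  expect_gt(max(abs(coords(m1) - coords(m2))), 0)
  rms <- superpose_rmsd(coords(m1, "CA"), coords(m2, "CA"))$rmsd
  expect_lte(rms, 0.5)
})

test_that("targets longer than the template get placed tail residues", {
  s <- build_peptide("GALSVEKFDTGA", "helix")
  tmpl <- build_peptide("GALSVEKF", "helix")   # 4 residues shorter
  tmpl$id <- "tmpl"
  aln <- new_joined_alignment(s$id, list(new_pairwise_alignment(
    s$id, "tmpl", structure_sequence(s), "GALSVEKF----")))
  m <- initialize_model(aln, list(tmpl), s, seed = 3)
  ## every tail residue exists and its N-CA bond length is sane
  a <- m$atoms
  for (r in 9:12) {
    rows <- which(a$res_index == r)
    expect_true(all(c("N", "CA") %in% a$atom_name[rows]))
    X <- coords(m)
    d <- sqrt(sum((X[rows[a$atom_name[rows] == "N"], ] -
                     X[rows[a$atom_name[rows] == "CA"], ])^2))
    expect_lt(abs(d - 1.458), 0.5)
  }
})

test_that("optimization is deterministic and monotone across phases", {
  pair <- std_pair(seed = 20, length = 12)
  rs <- set_optimal_sigma(build_hddrs(pair$aln, pair$templates, pair$native),
                          pair$native)
  proto <- optimization_protocol("very_fast", cg_iter = 60L,
                                 schedule = list(c(1.0, 10), c(0.2, 10)))
  init <- initialize_model(pair$aln, pair$templates, pair$native, seed = 4)
  r1 <- optimize_model(init, rs, protocol = proto, seed = 9)
  r2 <- optimize_model(init, rs, protocol = proto, seed = 9)
  expect_identical(coords(r1$model), coords(r2$model))
  expect_lte(r1$trace$F_TOT[nrow(r1$trace)], r1$trace$F_TOT[1])
})

test_that("stereochemistry-only optimization keeps ideal bond lengths", {
  s <- build_peptide("GALSVE", "extended")
  set.seed(12)
  start <- set_coords(s, coords(s) +
                        matrix(rnorm(3 * nrow(s$atoms), 0, 0.08), ncol = 3))
  res <- optimize_model(start, restraints = NULL,
                        protocol = optimization_protocol(
                          "very_fast", cg_iter = 400L,
                          schedule = list()),
                        seed = 2)
  X <- coords(res$model)
  b <- hddr:::topology_bonds(res$model)
  d <- sqrt(rowSums((X[b[, "i"], , drop = FALSE] -
                       X[b[, "j"], , drop = FALSE])^2))
  expect_lt(max(abs(d - b[, "r0"])), 0.02)
})

test_that("unfloored near-zero sigmas abort on the objective ceiling", {
  pair <- std_pair(seed = 42, length = 24, divergence = 1.5,
                   aln_error = 0.05)
  rs <- set_optimal_sigma(build_hddrs(pair$aln, pair$templates, pair$native),
                          pair$native)
  expect_gt(sum(rs$entries$abs_ddn < 1e-9), 0)  # conserved-core zeros exist
  rs_raw <- rs
  rs_raw$entries$sigma <- pmax(rs_raw$entries$abs_ddn, 1e-9)
  rs_raw <- set_weights(rs_raw, "only_lowest")
  init <- initialize_model(pair$aln, pair$templates, pair$native, seed = 1)
  expect_error(optimize_model(init, rs_raw),
               class = "hddr_objective_ceiling_error")
  ## the 0.05 A floor prevents the failure
  expect_no_error(optimize_model(init, rs,
                                 protocol = optimization_protocol(
                                   "very_fast", cg_iter = 40L,
                                   schedule = list(c(0.5, 5)))))
})

test_that("generate_decoys seeds reproducibly and records failures", {
  pair <- std_pair(seed = 23, length = 12)
  rs <- set_optimal_sigma(build_hddrs(pair$aln, pair$templates, pair$native),
                          pair$native)
  proto <- optimization_protocol("very_fast", cg_iter = 40L,
                                 schedule = list(c(0.5, 5)))
  d1 <- generate_decoys(pair$aln, pair$templates, pair$native, rs,
                        protocol = proto, n_decoys = 2, base_seed = 5)
  d2 <- generate_decoys(pair$aln, pair$templates, pair$native, rs,
                        protocol = proto, n_decoys = 2, base_seed = 5)
  expect_identical(coords(d1$decoys[[1]]), coords(d2$decoys[[1]]))
  expect_identical(coords(d1$decoys[[2]]), coords(d2$decoys[[2]]))
  expect_false(identical(coords(d1$decoys[[1]]), coords(d1$decoys[[2]])))
  expect_equal(d1$failed, 0L)
  ## n_decoys = 1: the average equals the single decoy's score
  d3 <- generate_decoys(pair$aln, pair$templates, pair$native, rs,
                        protocol = proto, n_decoys = 1, base_seed = 5)
  qr <- quality_report(d3$decoys, pair$native)
  expect_equal(unname(qr$average["gdt_ha"]), qr$per_decoy$gdt_ha[1])
})
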