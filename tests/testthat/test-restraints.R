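make_identity_setup <- function(seq1, fold = "extended") {
  s <- build_peptide(seq1, fold)
  tmpl <- s; tmpl$id <- "tmpl"
  aln <- new_joined_alignment(s$id, list(
    new_pairwise_alignment(s$id, "tmpl", seq1, seq1)))
  list(s = s, tmpl = tmpl, aln = aln)
}

test_that("gaussian_objective_term matches its closed forms", {
  expect_equal(gaussian_objective_term(4, 4, 1), log(sqrt(2 * pi)))
  expect_equal(gaussian_objective_term(4, 4, 1), 0.918939, tolerance = 1e-6)
  ## a one-sigma deviation adds exactly 0.5
  expect_equal(gaussian_objective_term(5, 4, 1), 0.918939 + 0.5,
               tolerance = 1e-6)
  ## frozen from -log(dnorm(5, 4, 0.5))
  expect_equal(gaussian_objective_term(5, 4, 0.5), 2.2257913526,
               tolerance = 1e-9)
  expect_error(gaussian_objective_term(5, 4, 0), "sigma")
})

test_that("harmonic identity holds exactly for arbitrary inputs", {
  set.seed(1)
  for (k in 1:20) {
    d_m <- runif(1, 1, 20); d_t <- runif(1, 1, 20); s <- runif(1, 0.05, 3)
    expect_equal(
      gaussian_objective_term(d_m, d_t, s) - gaussian_objective_term(d_t, d_t, s),
      (d_m - d_t)^2 / (2 * s^2), tolerance = 1e-12)
  }
})

test_that("mixture_density degenerates, symmetrizes, and matches its oracle", {
  ## U = 1 equals the single-Gaussian density
  expect_equal(mixture_density(5, 1, 4, 1), dnorm(5, 4, 1))
  ## symmetric two-component case collapses to a single standard normal
  expect_equal(mixture_density(5, c(0.7, 0.3), c(4, 6), c(1, 1)),
               dnorm(1), tolerance = 1e-9)
  ## frozen from the direct weighted sum 0.7*dnorm(4.5,4,.5)+0.3*dnorm(4.5,6,1)
  expect_equal(mixture_density(4.5, c(0.7, 0.3), c(4, 6), c(0.5, 1)),
               0.3776142931, tolerance = 1e-9)
  expect_error(mixture_density(4, c(0, 0), c(4, 5), c(1, 1)), "zero")
  expect_error(mixture_density(4, c(0.5, 0.2), c(4, 5), c(1, 1)), "sum to 1")
})

test_that("negative log mixture respects the component lower bound", {
  set.seed(7)
  for (k in 1:25) {
    U <- sample(2:4, 1)
    w <- runif(U); w <- w / sum(w)
    d_t <- runif(U, 3, 9); s <- runif(U, 0.1, 2); d_m <- runif(1, 2, 10)
    lhs <- -log(mixture_density(d_m, w, d_t, s))
    comp <- min(gaussian_objective_term(d_m, d_t, s))
    ## f = sum w_u phi_u <= max_u phi_u, so -ln f >= min_u obj_u, and a
    ## fortiori >= min_u obj_u + ln(max w_u)
    expect_gte(lhs, comp + log(max(w)) - 1e-9)
    expect_gte(lhs, comp - 1e-9)
  }
  ## equality when one weight is 1
  expect_equal(-log(mixture_density(5, 1, 4, 0.7)),
               gaussian_objective_term(5, 4, 0.7))
})

test_that("template_weights implements the three schemes", {
  expect_equal(template_weights("only_lowest", c(0.3, 0.7)), c(1, 0))
  expect_equal(template_weights("uniform", 1:4), rep(0.25, 4))
  ## tie: lowest template index wins
  expect_equal(template_weights("only_lowest", c(0.4, 0.4)), c(1, 0))
  w <- template_weights("similarity", c(0.8, 0.2, 0.01))
  expect_equal(sum(w), 1)
  expect_equal(w[3], 0.05 / (0.8 + 0.2 + 0.05))  # floored at 0.05
  expect_error(template_weights("uniform", numeric(0)), "empty")
})

test_that("build_hddrs counts pairs combinatorially on a tiny chain", {
  st <- make_identity_setup("GGG")
  ## with minimum separation 1 every Calpha pair is restrained: 3 pairs
  rs <- build_hddrs(st$aln, list(st$tmpl), st$s,
                    min_sep = c("CA-CA" = 1L, "N-O" = 1L,
                                "SCMC" = 1L, "SCSC" = 1L))
  caca <- rs$entries[rs$entries$group == "CA-CA", ]
  expect_equal(nrow(caca), 3L)
  expect_setequal(paste(caca$res_i, caca$res_j),
                  c("1 2", "1 3", "2 3"))
  ## default separation (2 for CA-CA) keeps only the 1-3 pair
  rs2 <- build_hddrs(st$aln, list(st$tmpl), st$s)
  expect_equal(nrow(rs2$entries[rs2$entries$group == "CA-CA", ]), 1L)
})

test_that("template coverage drives multi-template entry merging", {
  s <- build_peptide("GGGG", "extended")
  t1 <- build_peptide("GGG", "extended", id = "t1")  # aligns to 1-3
  t2 <- build_peptide("GGG", "extended", id = "t2")  # aligns to 2-4
  aln <- new_joined_alignment(s$id, list(
    new_pairwise_alignment(s$id, "t1", "GGGG", "GGG-"),
    new_pairwise_alignment(s$id, "t2", "GGGG", "-GGG")))
  rs <- build_hddrs(aln, list(t1, t2), s,
                    min_sep = c("CA-CA" = 1L, "N-O" = 1L,
                                "SCMC" = 1L, "SCSC" = 1L))
  e <- rs$entries[rs$entries$group == "CA-CA", ]
  u_23 <- sort(e$u[e$res_i == 2 & e$res_j == 3])
  u_12 <- e$u[e$res_i == 1 & e$res_j == 2]
  expect_equal(u_23, c(1L, 2L))  # both templates cover (2,3)
  expect_equal(u_12, 1L)         # only template 1 covers (1,2)
})

test_that("template distances above the group ceiling are dropped", {
  st <- make_identity_setup(strrep("G", 12), fold = "extended")
  ## extended chain: residues 1 and 12 are far apart
  d_full <- build_hddrs(st$aln, list(st$tmpl), st$s,
                        cutoffs = c("CA-CA" = 100, "N-O" = 11,
                                    "SCMC" = 6.5, "SCSC" = 6.5))
  d_cut <- build_hddrs(st$aln, list(st$tmpl), st$s)
  n_full <- sum(d_full$entries$group == "CA-CA")
  n_cut <- sum(d_cut$entries$group == "CA-CA")
  expect_gt(n_full, n_cut)
  expect_true(all(d_cut$entries$d_t[d_cut$entries$group == "CA-CA"] <= 14))
})

test_that("build_hddrs is invariant to template order up to relabeling", {
  pair <- std_pair(seed = 9, length = 14, n_templates = 2)
  rs_ab <- build_hddrs(pair$aln, pair$templates, pair$native)
  aln_rev <- new_joined_alignment(pair$aln$target_id,
                                  rev(pair$aln$alignments))
  rs_ba <- build_hddrs(aln_rev, rev(pair$templates), pair$native)
  key <- function(rs) {
    e <- rs$entries
    e <- e[order(e$group, e$ai, e$aj, e$template_id), ]
    paste(e$group, e$ai, e$aj, e$template_id, round(e$d_t, 6))
  }
  expect_identical(key(rs_ab), key(rs_ba))
})

test_that("restraint TSV round trips against the model topology", {
  pair <- std_pair(seed = 4, length = 12)
  rs <- set_optimal_sigma(build_hddrs(pair$aln, pair$templates, pair$native),
                          pair$native)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_restraints(rs, path)
  rs2 <- read_restraints(path, pair$native)
  expect_equal(nrow(rs2$entries), nrow(rs$entries))
  expect_equal(sort(rs2$entries$sigma), sort(rs$entries$sigma),
               tolerance = 1e-6)
})

test_that("weights always sum to 1 within each restraint", {
  pair <- std_pair(seed = 2, length = 14, n_templates = 3)
  for (scheme in c("uniform", "only_lowest", "similarity")) {
    rs <- set_weights(build_hddrs(pair$aln, pair$templates, pair$native),
                      scheme)
    sums <- tapply(rs$entries$w, rs$entries$rid, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})
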