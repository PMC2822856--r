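# Statistical pair potential: counting, derivation and complex scoring.

test_that("pair counting honours the separation filter and binning", {
  # two residues at sequence separation 5: excluded
  m <- make_centroid_model(c("LYS", "ASP"), rbind(c(0, 0, 0), c(5, 0, 0)),
                           resno = c(3, 8))
  pc <- count_pairs(list(m), bin_width = 0.25, max_distance = 20,
                    separation_min = 10)
  expect_equal(sum(pc$counts), 0)

  # separation 10 at 7.4 A: lands in bin floor(7.4/0.25) = 29 (0-based)
  m2 <- make_centroid_model(c("LYS", rep("GLY", 9), "ASP"),
                            cbind(c(0, 20 * 2:10, 7.4), 0, 0))
  pc2 <- count_pairs(list(m2), bin_width = 0.25, max_distance = 20,
                     separation_min = 10)
  expect_equal(pc2$counts["LYS", "ASP", 29 + 1], 1)
  expect_equal(pc2$counts["ASP", "LYS", 29 + 1], 1)   # symmetric storage

  # inter-chain pairs carry no separation filter
  m3 <- make_centroid_model(c("ALA", "TRP"), rbind(c(0, 0, 0), c(3, 0, 0)),
                            chain = c("A", "B"), resno = c(1, 1))
  pc3 <- count_pairs(list(m3), separation_min = 10)
  expect_equal(sum(pc3$counts["ALA", "TRP", ]), 1)

  expect_error(count_pairs(list()), "empty")
  mca <- make_centroid_model("ALA", rbind(c(0, 0, 0)), scheme = "CA")
  expect_error(count_pairs(list(m, mca)), "scheme")
})

test_that("pair counting matches an exhaustive double loop", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 12
    m <- make_centroid_model(sample(AA3, n, TRUE),
                             matrix(runif(3 * n, 0, 15), ncol = 3))
    pc <- count_pairs(list(m), bin_width = 1, max_distance = 12,
                      separation_min = 3)
    oracle <- count_pairs_oracle(m, 1, 12, 3)
    expect_equal(unname(pc$counts), oracle)
  }
})

test_that("potential derivation implements the log-odds with its fallbacks", {
  # uniform counts: every pair's distance distribution equals the marginal,
  # so u = 0 in every populated bin
  nbins <- 4
  counts <- array(0, dim = c(20, 20, nbins), dimnames = list(AA3, AA3, NULL))
  for (k in 1:nbins) counts[, , k] <- matrix(k, 20, 20)   # same shape for all
  pc <- structure(list(counts = counts, bin_width = 5, max_distance = 20,
                       separation_min = 10, scheme = "CM", n_structures = 1),
                  class = "pair_count_table")
  pot <- derive_potential(pc)
  for (k in 2:nbins) {
    expect_equal(max(abs(pot$u[, , k])), 0, tolerance = 1e-12)
  }

  # a pair observed at twice the expected frequency scores -ln 2
  counts2 <- counts
  counts2["LYS", "ASP", 2] <- 2 * counts2["LYS", "ASP", 2]
  counts2["ASP", "LYS", 2] <- counts2["LYS", "ASP", 2]
  pc2 <- structure(list(counts = counts2, bin_width = 5, max_distance = 20,
                        separation_min = 10, scheme = "CM", n_structures = 1),
                   class = "pair_count_table")
  pot2 <- derive_potential(pc2)
  # P_obs = 4/14 vs P_exp marginally perturbed; compute the exact expectation
  pair_tot <- sum(counts2["LYS", "ASP", ])
  tot <- sapply(1:nbins, function(k) {
    m <- counts2[, , k]; (sum(m) + sum(diag(m))) / 2
  })
  expected <- -log((counts2["LYS", "ASP", 2] / pair_tot) /
                     (tot[2] / sum(tot)))
  expect_equal(pot2$u["LYS", "ASP", 2], expected, tolerance = 1e-12)
  expect_lt(expected, -0.5)   # near -ln 2 (damped by the shifted pair total)
  expect_equal(pot2$u["LYS", "ASP", 2], pot2$u["ASP", "LYS", 2])

  # zero-observation bins carry the repulsive cap
  counts3 <- counts
  counts3["TRP", "CYS", ] <- 0; counts3["CYS", "TRP", ] <- 0
  pc3 <- structure(list(counts = counts3, bin_width = 5, max_distance = 20,
                        separation_min = 10, scheme = "CM", n_structures = 1),
                   class = "pair_count_table")
  expect_true(all(derive_potential(pc3)$u["TRP", "CYS", ] == 3.0))

  empty <- structure(list(counts = array(0, c(20, 20, 4)), bin_width = 5,
                          max_distance = 20, separation_min = 10,
                          scheme = "CM", n_structures = 0),
                     class = "pair_count_table")
  expect_error(derive_potential(empty), "empty")
})

test_that("sub-steric queries return the steric penalty of 2.0", {
  m <- make_centroid_model(rep(c("ALA", "GLY"), 30),
                           matrix(runif(180, 0, 18), ncol = 3))
  pot <- derive_potential(count_pairs(list(m), separation_min = 1))
  expect_equal(potential_at(pot, "ALA", "GLY", 0.5), 2.0)
  expect_equal(potential_at(pot, "LYS", "ASP", 0.99), 2.0)
  expect_equal(potential_at(pot, "K", "D", 0.2), 2.0)   # one-letter codes too
  # at-or-beyond max distance contributes nothing
  expect_equal(potential_at(pot, "ALA", "GLY", 25), 0)
})

test_that("complex scoring matches exhaustive enumeration and is additive", {
  set.seed(77)
  train <- make_potential_training_set(5, seed = 3,
                                       length_range = c(60, 80))
  pot <- derive_potential(count_pairs(train, bin_width = 1))

  pep <- make_centroid_model(sample(AA3, 3, TRUE),
                             matrix(runif(9, 0, 8), ncol = 3), chain = "P")
  mhc <- make_centroid_model(sample(AA3, 4, TRUE),
                             matrix(runif(12, 0, 8), ncol = 3), chain = "M")
  res <- score_complex(pep, mhc, pot, cutoff = 7.5)
  oracle <- score_complex_oracle(pep, mhc, pot, 7.5)
  expect_equal(res$raw, oracle$raw, tolerance = 1e-12)
  expect_equal(res$n_pairs, oracle$n_pairs)
  expect_equal(res$score, -res$raw)

  # no pair within cutoff: zero
  far <- make_centroid_model("ALA", rbind(c(100, 0, 0)), chain = "M")
  expect_equal(score_complex(pep, far, pot, cutoff = 7.5)$raw, 0)

  # additivity over disjoint peptide subsets
  pep1 <- pep[1, , drop = FALSE]; pep2 <- pep[2:3, , drop = FALSE]
  for (p in list(pep1, pep2)) {
    attr(p, "scheme") <- "CM"
  }
  attr(pep1, "scheme") <- attr(pep2, "scheme") <- "CM"
  class(pep1) <- class(pep2) <- c("centroid_model", "data.frame")
  expect_equal(score_complex(pep1, mhc, pot)$raw +
                 score_complex(pep2, mhc, pot)$raw,
               score_complex(pep, mhc, pot)$raw, tolerance = 1e-12)

  # cutoff monotonicity: contributing pairs grow with the cutoff
  n1 <- score_complex(pep, mhc, pot, cutoff = 5)$n_pairs
  n2 <- score_complex(pep, mhc, pot, cutoff = 9)$n_pairs
  expect_lte(n1, n2)

  # scheme mismatch is an error
  pep_ca <- make_centroid_model("ALA", rbind(c(0, 0, 0)), scheme = "CA")
  expect_error(score_complex(pep_ca, mhc, pot), "scheme")
})

test_that("derived potentials are symmetric and round-trip through TSV", {
  train <- make_potential_training_set(3, seed = 9, length_range = c(50, 70))
  pot <- derive_potential(count_pairs(train, bin_width = 2.5))
  for (k in seq_len(dim(pot$u)[3])) {
    expect_equal(pot$u[, , k], t(pot$u[, , k]))
  }
  path <- tempfile(fileext = ".tsv")
  write_potential(pot, path)
  pot2 <- read_potential(path)
  expect_equal(pot2$u, pot$u, tolerance = 1e-8)
  expect_equal(pot2$bin_width, pot$bin_width)
  expect_equal(pot2$scheme, pot$scheme)
})
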