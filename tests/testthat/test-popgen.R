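test_that("Watterson's theta reproduces the published table rows", {
  expect_equal(round(watterson_theta(0.570, 16), 3), 0.172)
  expect_equal(round(watterson_theta(0.357, 4), 3), 0.195)
})

test_that("Tajima's D matches the brute-force oracle on random data", {
  set.seed(17)
  for (i in 1:10) {
    m <- sample(4:8, 1)
    n <- sample(20:100, 1)
    nuc <- matrix(sample(c("A", "C", "G", "T"), m * n, replace = TRUE,
                         prob = c(0.4, 0.3, 0.2, 0.1)), m, n)
    # make some columns monomorphic so S < n
    mono <- sample(n, ceiling(n / 2))
    nuc[, mono] <- matrix(rep(nuc[1, mono], each = m), m)
    res <- tajima_d(nuc)
    orc <- oracle_tajima(nuc)
    expect_equal(res$S, orc$S)
    expect_equal(res$pi, orc$pi, tolerance = 1e-12)
    expect_equal(res$D, orc$D, tolerance = 1e-9)
    expect_equal(res$theta, res$ps / res$a1, tolerance = 1e-12)
  }
})

test_that("identical sequences give S = 0 and an undefined D", {
  aln <- codon_alignment(matrix("ATG", 4, 10,
                                dimnames = list(letters[1:4], NULL)))
  res <- tajima_d(aln)
  expect_equal(res$S, 0L)
  expect_true(is.na(res$D))
  expect_match(res$note, "no segregating sites")
})

test_that("Tajima's D applies complete deletion to codon alignments", {
  sim <- simulate_alignment(sim_config(tree6(), n_codons = 100, seed = 23,
                                       gap_fraction = 0.1))
  res <- tajima_d(sim$alignment)
  clean <- complete_deletion(sim$alignment)
  expect_equal(res$n_sites, 3L * site_count(clean))
  expect_equal(res$m, 6L)
})

test_that("NG86 handles identical and synonymous-only divergence", {
  s <- strrep("ATGGCACTGAAGGAT", 4)
  r0 <- ng86(s, s)
  expect_equal(r0$Ka, 0)
  expect_equal(r0$Ks, 0)
  expect_true(is.na(r0$Ka_Ks))
  # single synonymous difference (TTT -> TTC) inside a longer pair
  a <- paste0(s, "TTT")
  b <- paste0(s, "TTC")
  r1 <- ng86(a, b)
  expect_equal(r1$Ka, 0)
  expect_gt(r1$Ks, 0)
  expect_equal(r1$Sd, 1)
  expect_equal(r1$Nd, 0)
})

test_that("NG86 counts equal the exhaustive pathway-enumeration oracle", {
  set.seed(29)
  for (i in 1:4) {
    n <- 60L
    ca <- sample(sense_codons(), n, replace = TRUE)
    cb <- ca
    idx <- sample(n, 10)
    for (j in idx) cb[j] <- sample(sense_codons(), 1)
    r <- ng86(ca, cb)
    orc <- oracle_ng86_counts(ca, cb)
    expect_equal(r$S_sites, orc$S_sites, tolerance = 1e-9)
    expect_equal(r$N_sites, orc$N_sites, tolerance = 1e-9)
    expect_equal(r$Sd, orc$Sd, tolerance = 1e-9)
    expect_equal(r$Nd, orc$Nd, tolerance = 1e-9)
  }
})

test_that("NG86 Ka/Ks is near 1 for neutrally simulated sequences", {
  # simulated under the estimator's own assumptions (no ts/tv bias)
  ratios <- vapply(1:3, function(seed) {
    phy <- ape::read.tree(text = "(a:0.15,b:0.15);")
    sim <- simulate_alignment(sim_config(phylo_tree(phy), kappa = 1,
      omega_scheme = list(type = "one-ratio", omega = 1),
      n_codons = 1000, seed = 900 + seed))
    r <- ng86(sim$alignment$codons["a", ], sim$alignment$codons["b", ])
    r$Ka_Ks
  }, 0)
  expect_lt(abs(mean(ratios) - 1), 0.10)
})

test_that("ages follow T = Ks / (2r) under the rice synonymous clock", {
  expect_equal(age_from_ks(0.041), 3.15, tolerance = 0.005)
  expect_equal(age_from_ks(0.192), 14.77, tolerance = 0.005)
  expect_equal(age_from_ks(0), 0)
  expect_equal(age_from_ks(0.13, rate = 1e-8), 6.5, tolerance = 1e-9)
})

test_that("the Ks bootstrap is deterministic and behaves with length", {
  s <- strrep("ATGGCACTGAAGGATCGT", 20)   # 120 codons
  r0 <- ks_confidence(s, s, n_boot = 50, seed = 1)
  expect_equal(r0$ci_half_width, 0)

  set.seed(33)
  sim <- simulate_alignment(sim_config(
    phylo_tree(ape::read.tree(text = "(a:0.1,b:0.1);")),
    omega_scheme = list(type = "one-ratio", omega = 0.3),
    n_codons = 400, seed = 77))
  A <- sim$alignment$codons["a", ]; B <- sim$alignment$codons["b", ]
  r1 <- ks_confidence(A, B, n_boot = 200, seed = 5)
  r1b <- ks_confidence(A, B, n_boot = 200, seed = 5)
  expect_identical(r1, r1b)
  # doubling the length shrinks the CI roughly by 1/sqrt(2)
  r_half <- ks_confidence(A[1:200], B[1:200], n_boot = 200, seed = 5)
  expect_lt(abs(r1$ci_half_width / r_half$ci_half_width - 1 / sqrt(2)),
            0.25 / sqrt(2))
})

test_that("bootstrap intervals cover the generating Ks", {
  covered <- 0L
  for (seed in 1:10) {
    sim <- simulate_alignment(sim_config(
      phylo_tree(ape::read.tree(text = "(a:0.08,b:0.08);")),
      omega_scheme = list(type = "one-ratio", omega = 0.4),
      n_codons = 300, seed = 1000 + seed))
    A <- sim$alignment$codons["a", ]; B <- sim$alignment$codons["b", ]
    # generating Ks: synonymous flux fraction times total divergence over
    # synonymous sites; use the realized counts as the ground truth
    sites <- ng86(A, B)
    true_sd <- sum(sim$truth$counts$nS)
    truth_ks <- true_sd / sites$S_sites   # realized events per syn site
    kc <- ks_confidence(A, B, n_boot = 300, seed = seed)
    covered <- covered +
      (abs(kc$ks - truth_ks) <= kc$ci_half_width + 1e-12)
  }
  expect_gte(covered, 8L)
})

test_that("the Fisher enrichment test matches its table construction", {
  r <- enrichment_test(1, 10, 0.10, 100)
  expect_equal(r$p, 1)
  expect_equal(unname(r$table[1, ]), c(1, 9))
  expect_equal(unname(r$table[2, ]), c(10, 90))

  r2 <- enrichment_test(7, 24, 0.10, 1000)
  expect_lt(r2$p, 0.05)
  expect_gt(r2$odds_ratio, 1)

  r3 <- enrichment_test(0, 10, 0, 100)   # zero-margin table
  expect_equal(r3$p, 1)
})
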