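test_that("np accounting links one-ratio, free-ratio and branch counts", {
  # every published one-ratio/free-ratio np pair satisfies np_free = 2np - 3
  one_ratio_np <- c(14L, 14L, 18L, 32L, 18L, 8L, 22L)
  free_np <- c(25L, 25L, 33L, 61L, 33L, 13L, 41L)
  expect_equal(free_ratio_np(one_ratio_np), free_np)
  # and the generic rule np = B + 1 + R reproduces both columns
  B <- one_ratio_np - 2L
  expect_equal(np_branch_model(B, 1L), one_ratio_np)
  expect_equal(np_branch_model(B, B), free_np)
})

test_that("LRT machinery reproduces published statistics and p-values", {
  r <- lrt(-1497.98, -1491.98, df = 2)
  expect_equal(r$stat, 12.00, tolerance = 1e-9)
  expect_equal(r$p, 0.0025, tolerance = 0.01)   # printed to 2 s.f.
  expect_equal(lrt(-5, -5, df = 1)$stat, 0)
  expect_equal(lrt(-5, -5, df = 1)$p, 1)
  expect_error(lrt(-5, -6, df = 1), "nesting error")

  expect_equal(chi_square_sf(5.17, 1), 0.023, tolerance = 0.005)
  expect_equal(chi_square_sf(12.00, 2), 0.0025, tolerance = 0.01)
  expect_equal(chi_square_sf(16.62, 2), 2.461e-4, tolerance = 1e-3)
  expect_equal(chi_square_sf(0, 5), 1)
  # df = 2 upper tail is exactly exp(-x/2)
  expect_equal(chi_square_sf(7.3, 2), exp(-7.3 / 2), tolerance = 1e-12)
})

test_that("AIC is 2np - 2lnL and orders candidates", {
  f1 <- list(lnL = -1000, np = 14)
  expect_equal(aic(f1), 2028)
  f2 <- list(lnL = -998, np = 20)
  expect_true(aic(f1) < aic(f2))
})

test_that("the substitution-count heuristic follows the >9 & 0 rule", {
  expect_true(nozawa_flag(16, 0))
  expect_false(nozawa_flag(9, 0))
  expect_false(nozawa_flag(19.5, 7.1))
  expect_true(nozawa_flag(10, 0.4))   # expectations, tolerance 0.5
  expect_false(nozawa_flag(10, 0.6))
})

test_that("lnL is monotone under partition refinement", {
  tr <- tree6()
  om <- rep(0.2, n_branches(tr))
  om[stem_branch(tr, "F")] <- 2.5
  sim <- simulate_alignment(sim_config(tr,
    omega_scheme = list(type = "branch", omega_map = om),
    n_codons = 400, seed = 21))
  one <- fit_partition(sim$alignment, tr)
  cls <- rep(1L, n_branches(tr)); cls[stem_branch(tr, "F")] <- 2L
  two <- fit_partition(sim$alignment, tr, branch_partition(cls),
                       init = list(tlen = one$branch_lengths_hat,
                                   kappa = one$kappa_hat,
                                   omega = c(one$omega_hat, 2)))
  free <- fit_partition(sim$alignment, tr, free_ratio_partition(tr),
                        init = list(tlen = two$branch_lengths_hat,
                                    kappa = two$kappa_hat,
                                    omega = two$omega_hat[cls]))
  expect_gte(two$lnL, one$lnL - 1e-6)
  expect_gte(free$lnL, two$lnL - 1e-6)
  expect_equal(one$np, n_branches(tr) + 2L)
  expect_equal(free$np, 2L * one$np - 3L)
  # the two-class fit separates foreground from background
  expect_gt(two$omega_hat[2], 1)
  expect_lt(two$omega_hat[1], 0.5)
  # per-branch counts are non-negative and sum to L*t per branch
  with(two, expect_true(all(counts$nN >= 0 & counts$nS >= 0)))
  expect_equal(two$counts$nN + two$counts$nS,
               400 * two$branch_lengths_hat, tolerance = 1e-6)
})

test_that("fixing a class near omega 1 gives a near-zero statistic", {
  tr <- tree6()
  sim <- simulate_alignment(sim_config(tr,
    omega_scheme = list(type = "one-ratio", omega = 1),
    n_codons = 400, seed = 31))
  fit <- fit_partition(sim$alignment, tr)
  res <- fix_model_test(sim$alignment, tr, fit$partition, 1L, fit = fit)
  expect_lt(res$stat, 3.84)
  expect_gt(res$p, 0.05)
  expect_equal(res$fit_null$np, fit$np - 1L)
})

test_that("select_final applies the comparison and tie-break rules", {
  mk <- function(lnL, classes, method, np = NULL) {
    part <- branch_partition(classes)
    structure(list(partition = part,
                   fit = list(lnL = lnL, np = 9 + 1 + part$R,
                              partition = part),
                   method = method, trail = data.frame()),
              class = "ModelSearchResult")
  }
  # equal class count: higher lnL wins (published two-ratio comparison)
  a <- mk(-1381.523869, c(1, 1, 1, 2, 1, 1, 1, 1, 1), "I")
  b <- mk(-1380.484048, c(1, 1, 2, 1, 1, 1, 1, 1, 1), "III")
  expect_equal(select_final(list(a, b))$fit$lnL, -1380.484048)
  expect_equal(select_final(list(b, a))$fit$lnL, -1380.484048)

  # nested with 2*dlnL = 5.17 on one extra class: richer model wins at 0.05
  base_cls <- c(1, 1, 1, 2, 1, 1, 1, 1, 1)
  rich_cls <- c(1, 1, 3, 2, 1, 1, 1, 1, 1)
  n1 <- mk(-999.367951, base_cls, "I")
  n2 <- mk(-999.367951 + 5.17 / 2, rich_cls, "III")
  expect_equal(select_final(list(n1, n2))$partition$R, 3L)
  # but an insignificant improvement keeps the smaller model
  n3 <- mk(-999.367951 + 1.0, rich_cls, "III")
  expect_equal(select_final(list(n1, n3))$partition$R, 2L)

  # identical results: first wins by tie-break
  i1 <- mk(-100, rep(1, 9), "I")
  i2 <- mk(-100, rep(1, 9), "I")
  expect_identical(select_final(list(i1, i2)), i1)
  expect_error(select_final(list()), "argument error")
})

test_that("search accepts true splits and stays calibrated under the null", {
  tr <- tree6()
  target <- stem_branch(tr, "F")
  om <- rep(0.2, n_branches(tr)); om[target] <- 3
  sim <- simulate_alignment(sim_config(tr,
    omega_scheme = list(type = "branch", omega_map = om),
    n_codons = 500, seed = 41))
  res <- obsm_search(sim$alignment, tr, "I")
  # trail ends at the reported model and accepted lnLs are non-decreasing
  acc <- res$trail[grepl("^accept", res$trail$decision) |
                     res$trail$action == "one-ratio", ]
  expect_true(all(diff(acc$lnL) > -1e-9))
  expect_equal(acc$lnL[nrow(acc)], res$fit$lnL, tolerance = 1e-6)
  expect_true(sum(res$partition$classes ==
                    res$partition$classes[target]) == 1L)

  # one-ratio simulations: all three methods keep a single class
  all_one <- 0L
  for (seed in 1:3) {
    simn <- simulate_alignment(sim_config(tr,
      omega_scheme = list(type = "one-ratio", omega = 0.3),
      n_codons = 300, seed = 600 + seed))
    base <- fit_partition(simn$alignment, tr)
    Rs <- vapply(c("I", "II", "III"), function(m)
      obsm_search(simn$alignment, tr, m, base = base)$partition$R, 0L)
    all_one <- all_one + all(Rs == 1L)
  }
  expect_gte(all_one, 2L)
})

test_that("the fixed-omega test rejects a strongly selected foreground", {
  tr <- tree6()
  target <- stem_branch(tr, "F")
  om <- rep(0.2, n_branches(tr)); om[target] <- 5
  sim <- simulate_alignment(sim_config(tr,
    omega_scheme = list(type = "branch", omega_map = om),
    n_codons = 500, seed = 51))
  cls <- rep(1L, n_branches(tr)); cls[target] <- 2L
  res <- fix_model_test(sim$alignment, tr, branch_partition(cls), 2L)
  expect_lt(res$p, 0.05)
  expect_equal(res$df, 1L)
})
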