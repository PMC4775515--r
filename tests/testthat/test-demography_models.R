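test_that("mismatch_observed is the normalized pairwise-difference histogram", {
  a <- make_aln(rep("ACGTACGT", 4))
  expect_equal(as.numeric(mismatch_observed(a)), 1)
  b <- make_aln(c("AAAAAAAA", "CCCCCAAA"))
  mm <- mismatch_observed(b)
  expect_equal(as.numeric(mm[names(mm) == "5"]), 1)
  # mean of the spectrum equals the mean pairwise difference count
  set.seed(14)
  r <- drop_mutations(simulate_genealogy(12), 0.02, 300)
  sp <- mismatch_observed(r)
  expect_equal(sum(as.integer(names(sp)) * sp),
               nucleotide_diversity(r)$mean_pairwise, tolerance = 1e-12)
})

test_that("constant-size mismatch expectation is geometric and sums to one", {
  f <- mismatch_expected_constant(1, 25, renormalize = FALSE)
  expect_equal(as.numeric(f), 0.5^(1:26), tolerance = 1e-12)
  for (th in c(0.3, 2, 9)) {
    expect_equal(sum(mismatch_expected_constant(th, 3000, renormalize = FALSE)),
                 1, tolerance = 1e-9)
  }
  # theta -> 0: all the mass at zero differences
  expect_gt(mismatch_expected_constant(1e-9, 10)[1], 1 - 1e-6)
})

test_that("expansion mismatch expectation nests and behaves at its limits", {
  # tau = 0: the whole history sits at the ancestral theta
  expect_equal(as.numeric(mismatch_expected_expansion(2, 10, 0, 40)),
               as.numeric(mismatch_expected_constant(2, 40)), tolerance = 1e-12)
  # full mass check
  expect_equal(sum(mismatch_expected_expansion(0.5, 50, 5, 400,
                                               renormalize = FALSE)),
               1, tolerance = 1e-6)
  # large tau, tiny theta0: Poisson-like wave centred near tau
  f <- mismatch_expected_expansion(0.01, 100, 12, 60)
  expect_lt(abs(which.max(f) - 1 - 12), 3)
  mu <- sum((0:60) * f)
  expect_lt(abs(mu - 12) / 12, 0.2)
  expect_error(mismatch_expected_expansion(5, 2, 1, 10), "theta1 >= theta0")
})

test_that("fit_expansion recovers tau and rejects spurious expansions", {
  # point mass at zero: tau-hat = 0
  f0 <- fit_expansion(c(1, 0, 0, 0, 0))
  expect_equal(f0$tau, 0)

  # recovery: sudden expansion tau = 5 (theta0 = 0.5, theta1 = 50, n = 25);
  # 30 replicates keep runtime modest, the mean must land within +/-30%
  set.seed(31)
  taus <- replicate(30, {
    tr <- simulate_genealogy(25, list(type = "stepchange", T = 5 / 50, ratio = 100))
    a <- drop_mutations(tr, 50 / 900, 900)
    fit_expansion(mismatch_observed(a))$tau
  })
  expect_lt(abs(mean(taus) - 5) / 5, 0.3)

  # constant-size data: the expansion fit must not beat constant size by much
  set.seed(32)
  gains <- replicate(20, {
    a <- drop_mutations(simulate_genealogy(20), 5 / 600, 600)
    ft <- fit_expansion(mismatch_observed(a))
    (ft$sse_constant - ft$sse_expansion) / max(ft$sse_constant, 1e-12)
  })
  # expansion nests constant size so SSE can only improve; the improvement on
  # null data should usually be small compared to expansion data
  set.seed(33)
  gains_exp <- replicate(20, {
    tr <- simulate_genealogy(20, list(type = "stepchange", T = 0.1, ratio = 100))
    a <- drop_mutations(tr, 50 / 600, 600)
    ft <- fit_expansion(mismatch_observed(a))
    (ft$sse_constant - ft$sse_expansion) / max(ft$sse_constant, 1e-12)
  })
  expect_gt(mean(gains_exp), mean(gains))
})

test_that("R2 and raggedness are computable and sane", {
  set.seed(41)
  a <- drop_mutations(simulate_genealogy(15), 0.01, 300)
  r2 <- r2_stat(a)
  expect_true(is.finite(r2) && r2 > 0)
  expect_true(is.na(r2_stat(make_aln(c("AAAA", "AAAA")))))
  expect_equal(raggedness(c(1)), 0)
  expect_gt(raggedness(c(0.5, 0, 0.5)), raggedness(c(0.34, 0.33, 0.33)))
})

test_that("date_expansion follows the divergence-rate arithmetic", {
  d <- date_expansion(2, 0.01, 1000)
  expect_equal(d$t_years, 2 / (0.01 * 1000) * 1e6)
  # doubling L halves t for fixed tau
  expect_equal(date_expansion(2, 0.01, 2000)$t_years, d$t_years / 2)
  expect_error(date_expansion(2, 0, 1000), "rate")
  g <- date_expansion(2, 0.01, 1000, g = 10, theta0 = 1, theta1 = 100)
  expect_equal(g$t_growth_units, log(100) / 10)
})

test_that("contraction_loglik nests to constant size and matches the oracle", {
  set.seed(51)
  a <- drop_mutations(simulate_genealogy(8), 4 / 300, 300)
  eta <- folded_sfs(a)
  th <- 4
  r1 <- contraction_loglik(a, th, 0, 0, n_genealogy_samples = 4000, seed = 1)
  # independent constant-size Monte-Carlo oracle
  set.seed(77)
  or <- oracle_sfs_lnl_constant(eta, 8, th, 4000)
  expect_lt(abs(r1$lnL - or), 3 * r1$mc_se + 0.05)

  # disjoint seed sets agree within Monte-Carlo error
  r2 <- contraction_loglik(a, th, 0, 0, n_genealogy_samples = 4000, seed = 2)
  expect_lt(abs(r1$lnL - r2$lnL), 3 * (r1$mc_se + r2$mc_se) + 0.05)

  expect_error(contraction_loglik(aln_subset(a, 1:2), th, 0, 0), "degenerate")
  expect_error(contraction_loglik(a, -1, 0, 0), "theta")
})

test_that("a strong recent contraction is visible in the likelihood", {
  # single decisive fixture (fuller recovery rates are exercised in the
  # acceptance suite): truth (T = 0.05, S = 2) vs constant size
  set.seed(61)
  tr <- simulate_genealogy(16, list(type = "event", T = 0.05, S = 2))
  a <- drop_mutations(tr, 8 / 600, 600)
  l_true <- contraction_loglik(a, 8, 0.05, 2, n_genealogy_samples = 3000, seed = 5)
  l_null <- contraction_loglik(a, 8, 0, 0, n_genealogy_samples = 3000, seed = 5)
  expect_gt(l_true$lnL, l_null$lnL)
})

test_that("fit_three_models is exactly nested and reports the Table-3 shape", {
  set.seed(71)
  loci <- lapply(1:3, function(i) drop_mutations(simulate_genealogy(10), 0.01, 450))
  names(loci) <- c("A", "B", "C")
  ft <- fit_three_models(loci, n_genealogy_samples = 300, seed = 11)
  expect_gte(ft$M2$lnL + 1e-9, ft$M1$lnL)
  expect_gte(ft$M3$lnL + 1e-9, ft$M2$lnL)
  expect_equal(ft$M1$n_params, 3)
  expect_equal(ft$M2$n_params, 5)
  expect_equal(ft$M3$n_params, 9)
  expect_equal(ft$lrt$df, c(2, 6, 4))
  expect_named(ft$M3$T_i, c("A", "B", "C"))
  expect_true(ft$winner %in% c("M1", "M2", "M3"))
})
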