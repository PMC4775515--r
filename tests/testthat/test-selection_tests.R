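test_that("mk_test builds the 2x2 table and both two-tailed conventions", {
  # proportional table via constructed alignments is hard to force exactly;
  # check the exact-test machinery against the enumeration oracle directly
  tabs <- list(matrix(c(5, 5, 5, 5), 2), matrix(c(2, 12, 10, 3), 2),
               matrix(c(0, 8, 9, 2), 2), matrix(c(7, 1, 2, 11), 2))
  for (tb in tabs) {
    expect_equal(fisher.test(tb)$p.value, oracle_fisher2x2(tb), tolerance = 1e-9)
  }

  # end-to-end on constructed coding alignments:
  # polymorphism: 1 syn (GGA/GGG) + 1 nonsyn (AAA/GAA) in the focal group;
  # divergence: 1 syn + 1 nonsyn fixed between groups
  focal <- make_aln(c("GGAAAAATTCCC", "GGGAAAATTCCC", "GGAGAAATTCCC"))
  other <- make_aln(c("GGAAAAATCACC", "GGAAAAATCACC"))  # ATC syn, ACC nonsyn
  mk <- mk_test(focal, list(focal, other))
  expect_equal(mk$Pn, 1L); expect_equal(mk$Ps, 1L)
  expect_equal(mk$Dn, 1L); expect_equal(mk$Ds, 1L)
  expect_equal(mk$p, 1)
  expect_equal(mk$NI, 1)

  # degenerate: no polymorphism at all -> zero column margin
  mono <- make_aln(c("GGAAAAATTCCC", "GGAAAAATTCCC"))
  expect_error(mk_test(mono, list(mono, other)), "degenerate")
})

test_that("mk p-values match hypergeometric enumeration over many margins", {
  set.seed(4)
  for (i in 1:25) {
    tb <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    expect_equal(fisher.test(tb)$p.value, oracle_fisher2x2(tb), tolerance = 1e-9)
    # doubled-tail convention is always >= the one-sided tail
    p1 <- min(phyper(tb[1, 1], sum(tb[1, ]), sum(tb[2, ]), sum(tb[, 1])),
              phyper(tb[1, 1] - 1, sum(tb[1, ]), sum(tb[2, ]), sum(tb[, 1]),
                     lower.tail = FALSE))
    expect_gte(poldiv:::mk_p_doubled(tb) + 1e-12, p1)
  }
})

test_that("heterozygote excess exact test matches enumeration/Monte-Carlo", {
  # HWE proportions: no excess signal
  expect_gt(heterozygote_excess_test(c(25, 50, 25))$p, 0.3)
  # everybody heterozygous: overwhelming excess
  expect_lt(heterozygote_excess_test(c(0, 40, 0))$p, 1e-6)
  expect_error(heterozygote_excess_test(c(0, 0, 0)), "no individuals")

  # (1, 38, 1): compare with a random-pairing Monte-Carlo null
  obs <- c(1, 38, 1)
  p_exact <- heterozygote_excess_test(obs)$p
  nA <- 2 * obs[1] + obs[2]; na <- 2 * obs[3] + obs[2]
  pool <- c(rep("A", nA), rep("a", na))
  set.seed(12)
  hets <- replicate(20000, {
    g <- matrix(sample(pool), ncol = 2)
    sum(g[, 1] != g[, 2])
  })
  expect_lt(abs(p_exact - mean(hets >= obs[2])), 0.02)
})

test_that("hka_loglik is a sum of Poisson terms with the stated structure", {
  dat <- data.frame(locus = c("l1", "l2"), S = c(10, 5), D = c(20, 8),
                    L = c(600, 300), n = c(10, 10), c = c(1, 1))
  a1 <- sum(1 / (1:9))
  th <- c(10 / (a1 * 600), 5 / (a1 * 300))
  Td <- 2
  lam_S <- th * c(600, 300) * a1
  lam_D <- th * c(600, 300) * (Td + 1)
  manual <- sum(dpois(c(10, 5), lam_S, log = TRUE)) +
    sum(c(20, 8) * log(lam_D) - lam_D - lgamma(c(20, 8) + 1))
  expect_equal(hka_loglik(dat, th, Td, marginal = "poisson"), manual,
               tolerance = 1e-12)
  # the coalescent marginal keeps the mean structure but is wider: it puts
  # more probability on outcomes far from the expectation
  far <- dat; far$S <- c(30, 1)
  expect_gt(hka_loglik(far, th, Td), hka_loglik(far, th, Td, marginal = "poisson"))

  # doubling theta with k halved leaves the polymorphism term invariant but
  # changes the divergence term
  l1 <- hka_loglik(dat, th, Td, k = c(1, 1), marginal = "poisson")
  l2 <- hka_loglik(dat, 2 * th, Td, k = c(0.5, 0.5), marginal = "poisson")
  pois_part <- function(theta, k) sum(dpois(c(10, 5), k * theta * c(600, 300) * a1, log = TRUE))
  expect_equal(pois_part(th, c(1, 1)), pois_part(2 * th, c(0.5, 0.5)))
  expect_false(isTRUE(all.equal(l1, l2)))

  expect_error(hka_loglik(dat, c(-1, 1), Td), "non-positive")
})

test_that("fit_mlhka nests correctly and recovers parameters", {
  # single-locus nesting identity: all-k-fixed likelihood is the plain
  # two-Poisson likelihood
  dat1 <- data.frame(locus = "l1", S = 12, D = 24, L = 600, n = 12, c = 1)
  f <- fit_mlhka(dat1)
  expect_equal(f$lnL, hka_loglik(dat1, f$theta, f$T_div), tolerance = 1e-9)

  # free_k = empty set reduces to the null fit
  dat <- data.frame(locus = c("l1", "l2", "l3"), S = c(12, 20, 6),
                    D = c(25, 50, 12), L = c(600, 900, 300),
                    n = c(12, 12, 12), c = c(1, 1, 1))
  null <- fit_mlhka(dat)
  expect_length(null$free_k, 0)
  alt <- fit_mlhka(dat, free_k = c("l1", "l2"))
  expect_gte(alt$lnL + 1e-6, null$lnL)

  # parameter recovery on data drawn from the model itself
  set.seed(6)
  a1 <- sum(1 / (1:19))
  th_true <- c(0.005, 0.01, 0.02, 0.008); Td <- 3
  L <- rep(1000, 4)
  errs <- replicate(60, {
    S <- rpois(4, th_true * L * a1)
    D <- rpois(4, th_true * L * (Td + 1))
    d <- data.frame(locus = paste0("l", 1:4), S = S, D = D, L = L,
                    n = 20, c = 1)
    ft <- fit_mlhka(d, marginal = "poisson")
    c(ft$T_div, ft$theta)
  })
  expect_lt(abs(mean(errs[1, ]) - Td) / Td, 0.15)
  for (i in 1:4) {
    expect_lt(abs(mean(errs[1 + i, ]) - th_true[i]) / th_true[i], 0.15)
  }
})

test_that("lrt computes the chi-square comparison and guards nesting", {
  m0 <- list(lnL = -10, n_free = 3)
  expect_equal(lrt(m0, m0)$statistic, 0)
  expect_equal(lrt(m0, m0)$p, 1)
  m1 <- list(lnL = -10 + 3.94 / 2, n_free = 4)
  r <- lrt(m0, m1)
  expect_equal(r$statistic, 3.94)
  expect_equal(r$df, 1)
  expect_lt(r$p, 0.05)
  expect_error(lrt(list(lnL = -5, n_free = 3), list(lnL = -9, n_free = 4)),
               "optimization failure")
})
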