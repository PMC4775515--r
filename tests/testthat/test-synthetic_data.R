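test_that("genealogy simulator matches coalescent theory", {
  set.seed(91)
  reps <- 4000
  stats2 <- replicate(reps, {
    tr <- simulate_genealogy(20)
    c(tree_tmrca(tr), tree_total_length(tr))
  })
  expect_lt(abs(mean(stats2[1, ]) - 2 * (1 - 1 / 20)) / (2 * (1 - 1 / 20)), 0.05)
  expect_lt(abs(mean(stats2[2, ]) - 2 * sum(1 / (1:19))) / (2 * sum(1 / (1:19))), 0.02)

  # n = 2 pairwise coalescence time is 1 on average
  set.seed(92)
  t2 <- replicate(4000, tree_tmrca(simulate_genealogy(2)))
  expect_lt(abs(mean(t2) - 1), 0.05)

  # strong recent contraction: near-star genealogies, pairwise-time variance
  # collapses relative to constant size
  set.seed(93)
  tco <- replicate(800, tree_tmrca(simulate_genealogy(10, list(type = "event", T = 0.1, S = 6))))
  tcn <- replicate(800, tree_tmrca(simulate_genealogy(10)))
  expect_lt(var(tco), var(tcn) / 4)
})

test_that("drop_mutations hits the Watterson expectation and codon contracts", {
  set.seed(94)
  n <- 20; L <- 600; theta_site <- 5 / L
  S <- replicate(3000, {
    a <- drop_mutations(simulate_genealogy(n), theta_site, L)
    attr(segregating_sites(a, classify = FALSE), "S")
  })
  expect_lt(abs(mean(S) - 5 * sum(1 / (1:19))) / (5 * sum(1 / (1:19))), 0.03)

  expect_equal(attr(segregating_sites(
    drop_mutations(simulate_genealogy(6), 0, 300), classify = FALSE), "S"), 0L)

  # syn_fraction = 1 forces pi_a = 0
  set.seed(95)
  for (i in 1:5) {
    a <- drop_mutations(simulate_genealogy(8), 0.02, 300, syn_fraction = 1)
    ng <- nei_gojobori_within(a)
    expect_equal(ng$nonsyn_diffs, 0)
  }
  # tiny L cannot host many mutations
  expect_error({set.seed(1); drop_mutations(simulate_genealogy(20), 10, 6)},
               "L too small")
})

test_that("the generator is bit-reproducible under a fixed seed", {
  s1 <- simulate_two_species(scenario_spec(n_per_species = 6, seed = 123))
  s2 <- simulate_two_species(scenario_spec(n_per_species = 6, seed = 123))
  for (l in names(s1)) expect_identical(s1[[l]]$aln$seqs, s2[[l]]$aln$seqs)
  d1 <- tempfile(); d2 <- tempfile()
  write_scenario(s1, d1); write_scenario(s2, d2)
  for (f in list.files(d1, pattern = "fasta")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_true(file.exists(file.path(d1, "manifest.json")))
})

test_that("two-species generator separates and mixes species as the split dictates", {
  # deep split: plenty of fixed differences, none with a shallow split
  deep <- simulate_two_species(scenario_spec(
    n_per_species = 8, loci = c(locus1 = 300), theta = 0.01, c_i = 1,
    split_T = 8, seed = 7))
  sp <- split_species(deep$locus1$aln)
  fd_deep <- nrow(fixed_differences(sp$Euc, sp$Eus))
  expect_gt(fd_deep, 5)

  shallow <- simulate_two_species(scenario_spec(
    n_per_species = 8, loci = c(locus1 = 300), theta = 0.01, c_i = 1,
    split_T = 0.01, seed = 8))
  sp2 <- split_species(shallow$locus1$aln)
  fd_shallow <- nrow(fixed_differences(sp2$Euc, sp2$Eus))
  expect_lt(fd_shallow, fd_deep)
})

test_that("private-polymorphism thinning starves the focal species' S", {
  base <- scenario_spec(n_per_species = 12, loci = c(l1 = 600, l2 = 600),
                        theta = 0.012, c_i = 1, split_T = 4)
  set.seed(100)
  S_ratio <- replicate(25, {
    sd1 <- sample.int(1e6, 1)
    thin <- simulate_two_species(scenario_spec(
      n_per_species = 12, loci = c(l1 = 600, l2 = 600), theta = 0.012,
      c_i = 1, split_T = 4, thin = list(species = "A", locus = "l1", factor = 0.1),
      seed = sd1))
    sA1 <- attr(segregating_sites(split_species(thin$l1$aln)$Euc, classify = FALSE), "S")
    sA2 <- attr(segregating_sites(split_species(thin$l2$aln)$Euc, classify = FALSE), "S")
    c(sA1, sA2)
  })
  expect_lt(mean(S_ratio[1, ]), 0.4 * mean(S_ratio[2, ]))
})

test_that("balanced allelic classes produce the balancing-selection signature", {
  set.seed(110)
  d_low_m <- replicate(15, {
    a <- simulate_balanced_lineages(8, 0.006, 900, m = 0.1,
                                    seed = sample.int(1e6, 1))
    tajimas_d(a)$D
  })
  d_high_m <- replicate(15, {
    a <- simulate_balanced_lineages(8, 0.006, 900, m = 50,
                                    seed = sample.int(1e6, 1))
    tajimas_d(a)$D
  })
  expect_gt(mean(d_low_m, na.rm = TRUE), mean(d_high_m, na.rm = TRUE))

  # low exchange: deep class divergence dominates within-class diversity
  a <- simulate_balanced_lineages(10, 0.002, 900, m = 0.02, seed = 9)
  cls <- attr(a, "lineage_class")
  g1 <- aln_subset(a, which(cls == 1)); g2 <- aln_subset(a, which(cls == 2))
  expect_gt(jc_divergence(g1, g2)$K_raw,
            (nucleotide_diversity(g1)$pi + nucleotide_diversity(g2)$pi) / 2)

  # pairing one allele per class makes everyone heterozygous at class-
  # diagnostic sites: the excess test fires
  expect_lt(heterozygote_excess_test(c(0, 10, 0))$p, 0.01)
})

test_that("generator statistics agree with theory for pi as well", {
  set.seed(120)
  pis <- replicate(2000, {
    a <- drop_mutations(simulate_genealogy(20), 5 / 600, 600)
    mut <- attr(a, "mutations")
    # pi from the mutation record (collision-free placement makes this exact)
    sum(2 * mut$carriers * (20 - mut$carriers)) / (20 * 19)
  })
  expect_lt(abs(mean(pis) - 5) / 5, 0.05)
  # the mutation-record shortcut equals the alignment computation
  set.seed(121)
  a <- drop_mutations(simulate_genealogy(10), 0.02, 300)
  mut <- attr(a, "mutations")
  expect_equal(sum(2 * mut$carriers * (10 - mut$carriers)) / (10 * 9),
               nucleotide_diversity(a)$mean_pairwise, tolerance = 1e-9)
})
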