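test_that("watterson_theta follows S/(a1 L)", {
  expect_equal(watterson_theta(2, 3, 100)$theta_w, 0.03)
  expect_equal(watterson_theta(4, 0, 500)$theta_w, 0)
  # n=26, S=16, L=892 (printed to 4 dp as 0.0047 in the classic table shape)
  expect_equal(round(watterson_theta(26, 16, 892)$theta_w, 4), 0.0047)
  expect_error(watterson_theta(1, 3, 100), ">=2")
})

test_that("nucleotide_diversity equals the brute-force pairwise average", {
  a <- make_aln(c(paste(rep("A", 100), collapse = ""),
                  paste(c(rep("A", 99), "C"), collapse = "")))
  expect_equal(nucleotide_diversity(a)$pi, 0.01)
  expect_equal(nucleotide_diversity(make_aln(rep("ACGTAC", 5)))$pi, 0)
  for (seed in 1:4) {
    r <- random_aln(8, 50, seed)
    expect_equal(nucleotide_diversity(r)$pi, oracle_pi(r$seqs), tolerance = 1e-12)
  }
})

test_that("haplotype_diversity is the sample-corrected gene diversity", {
  set.seed(11)
  seqs <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = ""), "")
  expect_equal(haplotype_diversity(make_aln(seqs))$Hd, 1)
  expect_equal(haplotype_diversity(make_aln(rep("ACG", 8)))$Hd, 0)
  # two haplotypes 3:1 in n=4: Hd = 4/3 * (1 - (9+1)/16) = 0.5
  h <- haplotype_diversity(make_aln(c("AAA", "AAA", "AAA", "AAC")))
  expect_equal(h$Hd, 0.5)
})

test_that("tajimas_d is zero when pi*L equals S/a1 and NA when S = 0", {
  # n=4, a1 = 11/6: 3 two-two sites (4 pair diffs each) + 8 singleton sites
  # (3 each) give k = 36/6 = 6 = S/a1 exactly, so D = 0
  m <- matrix("A", 4, 11)
  m[3:4, 1:3] <- "C"
  m[1, 4:11] <- "C"
  rownames(m) <- sprintf("ES%02d_All%d", (1:4 + 1) %/% 2, (1:4 - 1) %% 2 + 1)
  a <- new_alignment(m, poldiv:::parse_labels(rownames(m)))
  expect_equal(tajimas_d(a)$D, 0)
  expect_false(tajimas_d(make_aln(c("AAAA", "AAAA")))$defined)
  # spot check against an independent constant recomputation
  r <- random_aln(6, 60, seed = 3)
  td <- tajimas_d(r)
  k <- nucleotide_diversity(r)$mean_pairwise
  expect_equal(td$D, oracle_tajima_D(6, td$S, k))
})

test_that("mean Tajima's D on neutral simulations matches an independent null", {
  reps <- 800
  set.seed(101)
  d_pkg <- replicate(reps, {
    a <- drop_mutations(simulate_genealogy(10), 5 / 300, 300)
    tajimas_d(a)$D
  })
  # independent null: D recomputed from oracle genealogies and Poisson counts
  set.seed(202)
  d_oracle <- replicate(reps, {
    cl <- oracle_class_lengths(10)
    S <- rpois(1, 5 / 2 * sum(cl))
    if (S == 0) return(NA_real_)
    sizes <- sample(1:9, S, replace = TRUE, prob = cl / sum(cl))
    k <- sum(2 * sizes * (10 - sizes)) / (10 * 9)
    oracle_tajima_D(10, S, k)
  })
  expect_lt(abs(mean(d_pkg, na.rm = TRUE) - mean(d_oracle, na.rm = TRUE)), 0.1)
})

test_that("jc_divergence applies the Jukes-Cantor map and is symmetric", {
  g1 <- make_aln("ACGTACGTAC")
  g2 <- make_aln("ACGTACGTAC")
  expect_equal(jc_divergence(g1, g2)$K_JC, 0)
  # exactly 10% raw divergence -> closed form -(3/4) log(1 - 0.4/3)
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("C", 10), rep("A", 90)), collapse = "")
  d <- jc_divergence(make_aln(s1), make_aln(s2))
  expect_equal(d$K_raw, 0.1)
  expect_equal(d$K_JC, -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_equal(d$K_JC, 0.1073, tolerance = 1e-3)
  d2 <- jc_divergence(make_aln(s2), make_aln(s1))
  expect_equal(d$K_JC, d2$K_JC)
  # saturation guard
  sat <- paste(rep("C", 100), collapse = "")
  expect_error(jc_divergence(make_aln(s1), make_aln(sat)), "JC undefined")
})

test_that("fixed_differences reports monomorphic between-group changes", {
  # codon 2 differs AAA (K) vs GAA (E) in every sequence of each group
  gA <- make_aln(c("ATGAAAGGG", "ATGAAAGGG"))
  gB <- make_aln(c("ATGGAAGGG", "ATGGAAGGG"))
  fd <- fixed_differences(gA, gB)
  expect_equal(nrow(fd), 1)
  expect_equal(fd$pos, 4L)
  expect_equal(fd$class, "nonsynonymous")
  expect_equal(fd$aa_change, "K2E")
  # a polymorphic site is not fixed
  gC <- make_aln(c("ATGAAAGGG", "ATGGAAGGG"))
  expect_equal(nrow(fixed_differences(gC, gB)), 0)
})

test_that("Nei-Gojobori codon counting matches the standard code", {
  p <- ng_codon_pair("ATT", "ATC")  # both Ile
  expect_equal(p$syn_diffs, 1)
  expect_equal(p$nonsyn_diffs, 0)
  expect_equal(ng_codon_pair("ATG", "ATG")$syn_diffs, 0)
  expect_equal(ng_codon_pair("ATG", "ATG")$syn_sites_a, 0)  # Met: no syn sites
  # classic two-step pair TTT (Phe) -> GTA (Val): pathways average
  p2 <- ng_codon_pair("TTT", "GTA")
  expect_equal(p2$syn_diffs + p2$nonsyn_diffs, 2)
  # site counts: 4-fold third position codon has exactly 1 synonymous site
  expect_equal(ng_codon_pair("GGA", "GGA")$syn_sites_a, 1)
})

test_that("syn + nonsyn sites always sum to 3 per compared codon", {
  set.seed(5)
  sim <- drop_mutations(simulate_genealogy(6), 0.02, 300)
  ng <- nei_gojobori_within(sim)
  expect_equal(ng$syn_sites + ng$nonsyn_sites, 300, tolerance = 1e-9)
})

test_that("nei_gojobori flags internal stop codons by position", {
  bad <- make_aln(c("ATGTAAGGG", "ATGTAAGGG"))  # TAA at codon 2
  expect_error(nei_gojobori_within(bad), "stop codon 2")
})

test_that("sliding windows tile the gene and degenerate to the global value", {
  set.seed(8)
  a <- drop_mutations(simulate_genealogy(8), 0.03, 120)
  w <- sliding_window(a, "pi", window_bp = 120, step_bp = 120)
  expect_equal(nrow(w), 1)
  expect_equal(w$value, nucleotide_diversity(a)$pi)

  # uniform divergence: flat K profile equal to the global value
  s1 <- strsplit(paste(rep("ATG", 20), collapse = ""), "")[[1]]
  s2 <- s1; s2[seq(3, 60, by = 3)] <- "A"  # ATG -> ATA everywhere
  m1 <- matrix(s1, 1); rownames(m1) <- "ES01_All1"
  m2 <- matrix(s2, 1); rownames(m2) <- "EC01_All1"
  g1 <- new_alignment(m1, poldiv:::parse_labels(rownames(m1)))
  g2 <- new_alignment(m2, poldiv:::parse_labels(rownames(m2)))
  glob <- jc_divergence(g1, g2)$K_JC
  prof <- sliding_window(list(g1, g2), "K", window_bp = 12, step_bp = 12)
  expect_true(all(abs(prof$value - glob) < 1e-12))

  # zero-denominator windows are flagged, not dropped
  prof2 <- sliding_window(list(g1, g1), "Ka/Ks", window_bp = 12, step_bp = 12)
  expect_true(all(prof2$flag == "zero_denominator"))
  expect_error(sliding_window(a, "pi", window_bp = 1000), "window larger")
})
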