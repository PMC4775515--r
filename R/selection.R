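#' McDonald-Kreitman test
#'
#' Contrasts synonymous/nonsynonymous counts of polymorphic sites within a
#' focal sample (Pn, Ps) against fixed differences between two groups
#' (Dn, Ds) with a two-tailed Fisher exact test on the 2x2 table. Two
#' two-tailed conventions are reported: `p` (sum of all tables with
#' probability <= observed, R's `fisher.test`) and `p_doubled`
#' (min(1, 2 x smaller one-tail)). The neutrality index
#' `NI = (Pn/Ps)/(Dn/Ds)` is returned when defined.
#'
#' @param polymorphism_source alignment or list of alignments; polymorphic
#'   site classes are counted within each and summed ("pooled" mode is simply
#'   passing both species).
#' @param divergence_pair list of two alignments (the two groups) whose fixed
#'   differences supply Dn, Ds.
#' @return list of class `mk_table` with `Pn`, `Ps`, `Dn`, `Ds`, `p`,
#'   `p_doubled`, `NI`.
#' @export
mk_test <- function(polymorphism_source, divergence_pair) {
  alns <- if (inherits(polymorphism_source, "aln")) list(polymorphism_source)
          else polymorphism_source
  Pn <- 0L; Ps <- 0L
  for (a in alns) {
    st <- segregating_sites(a, classify = TRUE)
    Pn <- Pn + sum(st$class == "nonsynonymous", na.rm = TRUE)
    Ps <- Ps + sum(st$class == "synonymous", na.rm = TRUE)
  }
  fd <- fixed_differences(divergence_pair[[1]], divergence_pair[[2]])
  Dn <- sum(fd$class == "nonsynonymous", na.rm = TRUE)
  Ds <- sum(fd$class == "synonymous", na.rm = TRUE)
  tab <- matrix(c(Pn, Ps, Dn, Ds), 2, 2,
                dimnames = list(c("nonsyn", "syn"), c("polymorphic", "fixed")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: zero row or column margin (Pn=", Pn, " Ps=", Ps,
         " Dn=", Dn, " Ds=", Ds, ")")
  }
  ft <- stats::fisher.test(tab)
  p_doubled <- mk_p_doubled(tab)
  NI <- if (Ps > 0 && Dn > 0 && Ds > 0) (Pn / Ps) / (Dn / Ds) else NA_real_
  structure(list(Pn = Pn, Ps = Ps, Dn = Dn, Ds = Ds, table = tab,
                 p = ft$p.value, p_doubled = p_doubled, NI = NI),
            class = "mk_table")
}

# two-tailed by doubling the smaller one-sided hypergeometric tail
mk_p_doubled <- function(tab) {
  x <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- stats::phyper(x, m, n, k)
  hi <- stats::phyper(x - 1, m, n, k, lower.tail = FALSE)
  min(1, 2 * min(lo, hi))
}

#' @export
print.mk_table <- function(x, ...) {
  cat("<mk_table>\n")
  print(x$table)
  cat(sprintf("  p = %.4g (sum-of-small-tables), p = %.4g (doubled tail), NI = %.3g\n",
              x$p, x$p_doubled, x$NI))
  invisible(x)
}

#' Exact one-sided test for heterozygote excess
#'
#' Levene/Haldane exact conditional test: conditional on the observed allele
#' counts, the probability of each heterozygote count h is
#' `P(h) ∝ 2^h / (((nA-h)/2)! h! ((na-h)/2)!)`; the one-sided p-value sums
#' the probabilities of all configurations with at least the observed number
#' of heterozygotes.
#'
#' @param counts numeric vector `c(AA, Aa, aa)` of genotype counts.
#' @return list with `p`, `observed_het`, `expected_het` (HWE conditional
#'   expectation).
#' @export
heterozygote_excess_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  if (sum(counts) == 0) stop("no individuals")
  nAA <- counts[1]; nAa <- counts[2]; naa <- counts[3]
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  logw <- vapply(hs, function(h) {
    h * log(2) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) - lgamma((na - h) / 2 + 1)
  }, numeric(1))
  w <- exp(logw - max(logw))
  pr <- w / sum(w)
  list(p = sum(pr[hs >= nAa]),
       observed_het = nAa,
       expected_het = sum(hs * pr))
}
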