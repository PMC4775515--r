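#' Pairwise linkage disequilibrium and Kelly's ZnS
#'
#' Computes r-squared for every pair of biallelic segregating sites (on
#' pairwise-complete sequences), a two-tailed Fisher exact test on the 2x2
#' haplotype count table per pair, and the Bonferroni-corrected significance
#' at `alpha / n_pairs`. `ZnS` is the mean r-squared over the listed pairs
#' (Kelly 1997). By default all biallelic segregating sites enter (which
#' reproduces pair counts of `choose(S, 2)` on fully biallelic data);
#' `exclude_singletons = TRUE` restricts to sites with minor allele count >= 2.
#'
#' @param aln alignment.
#' @param alpha significance level before correction.
#' @param exclude_singletons drop sites whose minor allele is a singleton?
#' @return list of class `ld_result` with `pairs` data.frame (`pos_i`,
#'   `pos_j`, `r2`, `p`, `sig_raw`, `sig_bonferroni`), `ZnS`, `n_pairs`,
#'   `n_sig_raw`, `n_sig_bonferroni`.
#' @export
pairwise_ld <- function(aln, alpha = 0.05, exclude_singletons = FALSE) {
  m <- biallelic_matrix(aln, min_minor = if (exclude_singletons) 2L else 1L)
  pos <- attr(m, "pos")
  S <- ncol(m)
  if (S < 2) {
    warning("fewer than 2 eligible sites; empty LD result")
    return(structure(list(
      pairs = data.frame(pos_i = integer(0), pos_j = integer(0), r2 = numeric(0),
                         p = numeric(0), sig_raw = logical(0),
                         sig_bonferroni = logical(0)),
      ZnS = NA_real_, n_pairs = 0L, n_sig_raw = 0L, n_sig_bonferroni = 0L),
      class = "ld_result"))
  }
  prs <- t(utils::combn(S, 2))
  r2 <- numeric(nrow(prs)); p <- numeric(nrow(prs))
  for (k in seq_len(nrow(prs))) {
    x <- m[, prs[k, 1]]; y <- m[, prs[k, 2]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    tab <- table(factor(x, 0:1), factor(y, 0:1))
    pA <- mean(x); pB <- mean(y)
    Dld <- mean(x * y) - pA * pB
    den <- pA * (1 - pA) * pB * (1 - pB)
    r2[k] <- if (den > 0) Dld^2 / den else NA_real_
    p[k] <- stats::fisher.test(tab)$p.value
  }
  n_pairs <- nrow(prs)
  thr <- alpha / n_pairs
  pairs <- data.frame(pos_i = pos[prs[, 1]], pos_j = pos[prs[, 2]],
                      r2 = r2, p = p, sig_raw = p < alpha,
                      sig_bonferroni = p < thr)
  structure(list(pairs = pairs, ZnS = mean(r2, na.rm = TRUE),
                 n_pairs = n_pairs, n_sig_raw = sum(pairs$sig_raw),
                 n_sig_bonferroni = sum(pairs$sig_bonferroni)),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("<ld_result> ZnS = %.4f over %d pairs; %d significant raw, %d after Bonferroni\n",
              x$ZnS, x$n_pairs, x$n_sig_raw, x$n_sig_bonferroni))
  invisible(x)
}
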