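# Nei & Gojobori (1986) synonymous/nonsynonymous site and difference counting
# with equal pathway weighting. All 64x64 codon-pair results are precomputed at
# build time so sliding windows stay fast.

ng_tables <- local({
  codons <- names(GENETIC_CODE_STD)
  aa <- GENETIC_CODE_STD
  syn_sites <- setNames(numeric(64), codons)
  for (c0 in codons) {
    if (aa[c0] == "*") { syn_sites[c0] <- NA_real_; next }
    s <- 0
    for (p in 1:3) for (b in DNA_BASES) {
      if (substr(c0, p, p) == b) next
      c1 <- c0
      substr(c1, p, p) <- b
      # changes to stop codons count as nonsynonymous; each position always
      # contributes 1 total site so syn + nonsyn sites sum to 3 per codon
      if (aa[c1] != "*" && aa[c1] == aa[c0]) s <- s + 1 / 3
    }
    syn_sites[c0] <- s
  }
  sd <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  nd <- sd
  perms <- list(`1` = matrix(1, 1, 1),
                `2` = rbind(c(1, 2), c(2, 1)),
                `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
  step_class <- function(ca, cb) if (aa[ca] == aa[cb]) "s" else "n"
  for (ca in codons) for (cb in codons) {
    if (aa[ca] == "*" || aa[cb] == "*") next
    dpos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    d <- length(dpos)
    if (d == 0) { sd[ca, cb] <- 0; nd[ca, cb] <- 0; next }
    pm <- perms[[as.character(d)]]
    path_s <- numeric(0); path_n <- numeric(0); blocked_s <- numeric(0); blocked_n <- numeric(0)
    for (r in seq_len(nrow(pm))) {
      cur <- ca; s <- 0; n <- 0; blocked <- FALSE
      for (stp in seq_len(d)) {
        p <- dpos[pm[r, stp]]
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (aa[nxt] == "*" && stp < d) blocked <- TRUE
        if (aa[nxt] != "*" && aa[nxt] == aa[cur]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (blocked) { blocked_s <- c(blocked_s, s); blocked_n <- c(blocked_n, n) }
      else { path_s <- c(path_s, s); path_n <- c(path_n, n) }
    }
    if (length(path_s) == 0) { path_s <- blocked_s; path_n <- blocked_n }
    sd[ca, cb] <- mean(path_s)
    nd[ca, cb] <- mean(path_n)
  }
  list(syn_sites = syn_sites, sd = sd, nd = nd)
})

# codon strings per sequence; NA where a codon has non-ACGT characters.
# Errors on internal stop codons, naming the codon.
codon_strings <- function(aln) {
  cm <- codon_matrix(aln$seqs, aln$offset)
  out <- matrix(NA_character_, n_seq(aln), cm$n_codon,
                dimnames = list(rownames(aln$seqs), NULL))
  for (k in seq_len(cm$n_codon)) {
    cs <- cm$starts[k]
    cod <- apply(aln$seqs[, cs:(cs + 2), drop = FALSE], 1, paste, collapse = "")
    ok <- !grepl("[^ACGT]", cod)
    out[ok, k] <- cod[ok]
  }
  tr <- matrix(translate_codon(out), nrow = nrow(out))
  stops <- which(tr == "*", arr.ind = TRUE)
  stops <- stops[stops[, 2] < ncol(out), , drop = FALSE]  # terminal stop tolerated
  if (nrow(stops)) {
    stop(sprintf("internal stop codon %d in sequence '%s'",
                 stops[1, 2], rownames(out)[stops[1, 1]]))
  }
  out
}

# Nei-Gojobori proportions averaged over a set of sequence pairs.
# pairs: two-column matrix of row indices into (codA rows, codB rows).
ng_average <- function(codA, codB, pairs) {
  tb <- ng_tables
  Ssum <- 0; Nsum <- 0; Sd <- 0; Nd <- 0
  ps_vec <- numeric(nrow(pairs)); pn_vec <- numeric(nrow(pairs))
  Ss_vec <- numeric(nrow(pairs)); Ns_vec <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- codA[pairs[r, 1], ]; b <- codB[pairs[r, 2], ]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) { ps_vec[r] <- NA; pn_vec[r] <- NA; next }
    ssites <- (tb$syn_sites[a[ok]] + tb$syn_sites[b[ok]]) / 2
    S <- sum(ssites); N <- 3 * sum(ok) - S
    sdf <- sum(tb$sd[cbind(a[ok], b[ok])])
    ndf <- sum(tb$nd[cbind(a[ok], b[ok])])
    Ssum <- Ssum + S; Nsum <- Nsum + N; Sd <- Sd + sdf; Nd <- Nd + ndf
    Ss_vec[r] <- S; Ns_vec[r] <- N
    ps_vec[r] <- if (S > 0) sdf / S else NA
    pn_vec[r] <- if (N > 0) ndf / N else NA
  }
  npr <- nrow(pairs)
  jc <- function(p) ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
  ps <- mean(ps_vec, na.rm = TRUE); pn <- mean(pn_vec, na.rm = TRUE)
  list(syn_sites = Ssum / npr, nonsyn_sites = Nsum / npr,
       syn_diffs = Sd / npr, nonsyn_diffs = Nd / npr,
       ps = ps, pn = pn, ds = jc(ps), dn = jc(pn))
}

#' Nei-Gojobori within-sample synonymous/nonsynonymous diversity
#'
#' Pathway-counting of Nei & Gojobori (1986) with equal pathway weighting
#' (stop-traversing pathways excluded from the averaging) and Jukes-Cantor
#' correction. `pi_s`/`pi_a` are the JC-corrected mean pairwise proportions.
#'
#' @param aln coding alignment (frame set via its offset; internal stop codons
#'   raise an error naming the codon).
#' @return list with `syn_sites`, `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`
#'   (pair averages), `pi_s`, `pi_a`.
#' @export
nei_gojobori_within <- function(aln) {
  n <- n_seq(aln)
  if (n < 2) stop("need >=2 sequences")
  cod <- codon_strings(aln)
  pairs <- t(utils::combn(n, 2))
  r <- ng_average(cod, cod, pairs)
  list(syn_sites = r$syn_sites, nonsyn_sites = r$nonsyn_sites,
       syn_diffs = r$syn_diffs, nonsyn_diffs = r$nonsyn_diffs,
       pi_s = r$ds, pi_a = r$dn)
}

#' Nei-Gojobori between-group Ka and Ks
#'
#' @param group_a,group_b coding alignments of equal length and frame.
#' @return list with site/difference averages plus `Ka`, `Ks` (JC-corrected).
#' @export
nei_gojobori_between <- function(group_a, group_b) {
  codA <- codon_strings(group_a); codB <- codon_strings(group_b)
  pairs <- as.matrix(expand.grid(seq_len(nrow(codA)), seq_len(nrow(codB))))
  r <- ng_average(codA, codB, pairs)
  list(syn_sites = r$syn_sites, nonsyn_sites = r$nonsyn_sites,
       syn_diffs = r$syn_diffs, nonsyn_diffs = r$nonsyn_diffs,
       Ks = r$ds, Ka = r$dn)
}

#' Nei-Gojobori counts for a single codon pair
#'
#' Mostly a testing/inspection hook: pathway-averaged synonymous and
#' nonsynonymous difference counts and per-codon site counts.
#'
#' @param codon_a,codon_b 3-letter codons.
#' @return list with `syn_diffs`, `nonsyn_diffs`, `syn_sites_a`, `syn_sites_b`.
#' @export
ng_codon_pair <- function(codon_a, codon_b) {
  a <- toupper(codon_a); b <- toupper(codon_b)
  list(syn_diffs = ng_tables$sd[a, b], nonsyn_diffs = ng_tables$nd[a, b],
       syn_sites_a = unname(ng_tables$syn_sites[a]),
       syn_sites_b = unname(ng_tables$syn_sites[b]))
}
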