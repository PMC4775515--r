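#' Watterson's theta per site
#'
#' `theta_w = S / (a_{n-1} * L)` with `a_{n-1} = sum_{i=1}^{n-1} 1/i`. The
#' standard deviation uses the no-recombination variance of Watterson's
#' estimator (Tajima 1989 constants), matching the "+/- SD" convention of
#' classic polymorphism tables.
#'
#' @param n number of sampled alleles (>= 2).
#' @param S number of segregating sites.
#' @param L sequence length in bp (> 0).
#' @return list with `theta_w` (per site) and `sd` (per site).
#' @export
watterson_theta <- function(n, S, L) {
  if (n < 2) stop("need >=2 sequences")
  if (L <= 0) stop("L must be > 0")
  a1 <- harmonic(n - 1)
  a2 <- harmonic2(n - 1)
  th <- S / (a1 * L)
  # no-recombination variance: Var(theta_w) = theta/(a1*L) + a2*theta^2/a1^2
  v <- th / (a1 * L) + (a2 / a1^2) * th^2
  list(theta_w = th, sd = sqrt(v))
}

# per-site pairwise difference count for a pair, with pairwise deletion;
# returns c(diffs, sites_compared)
pair_diff <- function(x, y) {
  ok <- x %in% DNA_BASES & y %in% DNA_BASES
  c(sum(x[ok] != y[ok]), sum(ok))
}

#' Nucleotide diversity (pi) per site
#'
#' Mean over all unordered sequence pairs of the per-site proportion of
#' differences, with pairwise deletion of gap/N positions. The standard
#' deviation is the no-recombination (total) variance of Tajima (1983),
#' `Var(pi) = (b1/L) * pi + b2 * pi^2` with Tajima's b1, b2.
#'
#' @param aln alignment with `n >= 2`.
#' @return list with `pi`, `sd`, and `mean_pairwise` (mean raw pairwise
#'   difference count, the mean of the mismatch distribution).
#' @export
nucleotide_diversity <- function(aln) {
  n <- n_seq(aln)
  if (n < 2) stop("need >=2 sequences")
  s <- aln$seqs
  tot <- 0; totk <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pd <- pair_diff(s[i, ], s[j, ])
    if (pd[2] > 0) tot <- tot + pd[1] / pd[2]
    totk <- totk + pd[1]
    np <- np + 1
  }
  pi <- tot / np
  k <- totk / np
  cn <- tajima_constants(n)
  v <- cn$b1 * pi / aln_len(aln) + cn$b2 * pi^2
  list(pi = pi, sd = sqrt(v), mean_pairwise = k)
}

#' Haplotype (gene) diversity
#'
#' `Hd = n/(n-1) * (1 - sum p_i^2)` over haplotype frequencies. The variance
#' follows Nei (1987, eq. 8.12).
#'
#' @param aln alignment with `n >= 2`.
#' @return list with `Hd`, `sd`, `n_haplotypes`.
#' @export
haplotype_diversity <- function(aln) {
  n <- n_seq(aln)
  if (n < 2) stop("need >=2 sequences")
  h <- collapse_haplotypes(aln)
  p <- h$count / n
  Hd <- n / (n - 1) * (1 - sum(p^2))
  # Nei (1987) variance of heterozygosity
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sum(p^2)^2) + sum(p^2) - sum(p^2)^2)
  list(Hd = Hd, sd = sqrt(max(v, 0)), n_haplotypes = nrow(h))
}

#' Tajima's D
#'
#' `D = (k - S/a1) / sqrt(e1*S + e2*S*(S-1))` with k the mean pairwise
#' difference count and Tajima (1989) constants from n. Undefined (NA, with
#' `defined = FALSE`) when `S = 0`.
#'
#' @param aln alignment with `n >= 2`.
#' @return list with `D`, `defined`, `S`, `k`.
#' @export
tajimas_d <- function(aln) {
  n <- n_seq(aln)
  if (n < 2) stop("need >=2 sequences")
  st <- segregating_sites(aln, classify = FALSE)
  S <- attr(st, "S")
  k <- nucleotide_diversity(aln)$mean_pairwise
  if (S == 0) return(list(D = NA_real_, defined = FALSE, S = 0L, k = k))
  cn <- tajima_constants(n)
  D <- (k - S / cn$a1) / sqrt(cn$e1 * S + cn$e2 * S * (S - 1))
  # the variance constants vanish at n <= 3: D is undefined there
  list(D = D, defined = is.finite(D), S = S, k = k)
}

#' Per-locus, per-group diversity summary
#'
#' One row of the classic polymorphism table: n, L, S, Watterson's theta,
#' pi, Hd (each with SD) and Tajima's D.
#'
#' @param aln alignment for one species at one locus.
#' @param locus,group labels carried into the row.
#' @return one-row data.frame.
#' @export
locus_summary <- function(aln, locus = "locus", group = "group") {
  n <- n_seq(aln); L <- aln_len(aln)
  st <- segregating_sites(aln, classify = FALSE)
  S <- attr(st, "S")
  tw <- watterson_theta(n, S, L)
  pi <- nucleotide_diversity(aln)
  hd <- haplotype_diversity(aln)
  td <- tajimas_d(aln)
  data.frame(locus = locus, group = group, n = n, L = L, S = S,
             theta_w = tw$theta_w, theta_w_sd = tw$sd,
             pi = pi$pi, pi_sd = pi$sd,
             Hd = hd$Hd, Hd_sd = hd$sd,
             tajima_D = td$D, stringsAsFactors = FALSE)
}

#' Jukes-Cantor divergence between two groups
#'
#' `K_raw` is the mean between-group pairwise p-distance (pairwise deletion);
#' `K_JC = -(3/4) log(1 - (4/3) K_raw)`. Fixed differences (sites monomorphic
#' within each group but different between them) are enumerated with their
#' synonymous/nonsynonymous status and amino-acid change (1-based residue
#' numbers within the fragment). Net divergence Da = K_raw - mean within-group
#' diversity is logged alongside.
#'
#' @param group_a,group_b alignments of equal length.
#' @return list with `K_raw`, `K_JC`, `Da`, `fixed_differences` data.frame.
#' @export
jc_divergence <- function(group_a, group_b) {
  if (aln_len(group_a) != aln_len(group_b)) stop("alignments differ in length")
  if (n_seq(group_a) < 1 || n_seq(group_b) < 1) stop("empty group")
  sa <- group_a$seqs; sb <- group_b$seqs
  tot <- 0; np <- 0
  for (i in seq_len(nrow(sa))) for (j in seq_len(nrow(sb))) {
    pd <- pair_diff(sa[i, ], sb[j, ])
    if (pd[2] > 0) tot <- tot + pd[1] / pd[2]
    np <- np + 1
  }
  K_raw <- tot / np
  if (K_raw >= 0.75) stop("JC undefined: raw divergence >= 0.75")
  K_JC <- -0.75 * log(1 - 4 * K_raw / 3)
  piw <- function(g) if (n_seq(g) >= 2) nucleotide_diversity(g)$pi else 0
  Da <- K_raw - (piw(group_a) + piw(group_b)) / 2
  list(K_raw = K_raw, K_JC = K_JC, Da = Da,
       fixed_differences = fixed_differences(group_a, group_b))
}

#' Fixed differences between two groups
#'
#' @param group_a,group_b alignments of equal length (same reading frame).
#' @return data.frame with `pos` (1-based), `state_a`, `state_b`, `class`
#'   (synonymous/nonsynonymous/ambiguous), `residue` (1-based amino acid
#'   within the frame) and `aa_change` (e.g. `"N63D"`).
#' @export
fixed_differences <- function(group_a, group_b) {
  sa <- group_a$seqs; sb <- group_b$seqs
  off <- group_a$offset
  L <- ncol(sa)
  res <- list()
  for (j in seq_len(L)) {
    ca <- unique(sa[, j][sa[, j] %in% DNA_BASES])
    cb <- unique(sb[, j][sb[, j] %in% DNA_BASES])
    if (length(ca) == 1 && length(cb) == 1 && ca != cb) {
      cidx <- (j - 1 - off) %/% 3
      residue <- cidx + 1
      cls <- NA_character_; aach <- NA_character_
      if (cidx >= 0 && (L - off) %% 3 == 0) {
        cstart <- off + cidx * 3 + 1
        cons <- function(s) {
          apply(s[, cstart:(cstart + 2), drop = FALSE], 2, function(col) {
            t <- table(col[col %in% DNA_BASES])
            if (length(t)) names(t)[which.max(t)] else "N"
          })
        }
        coda <- paste(cons(sa), collapse = "")
        codb <- paste(cons(sb), collapse = "")
        aaa <- translate_codon(coda); aab <- translate_codon(codb)
        if (!is.na(aaa) && !is.na(aab)) {
          if (aaa == aab) cls <- "synonymous"
          else {
            cls <- "nonsynonymous"
            aach <- paste0(aaa, residue, aab)
          }
        }
      }
      res[[length(res) + 1]] <- data.frame(
        pos = j, state_a = ca, state_b = cb, class = cls,
        residue = residue, aa_change = aach, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(pos = integer(0), state_a = character(0),
                      state_b = character(0), class = character(0),
                      residue = integer(0), aa_change = character(0)))
  }
  do.call(rbind, res)
}

#' Sliding-window profile of a statistic along the alignment
#'
#' Windows tile `[1, L]` with the given width and step; the statistic is
#' recomputed on the window's columns. Ratio statistics with a zero
#' denominator are flagged (`flag = "zero_denominator"`), never dropped.
#'
#' @param aln alignment (for `K`, `Ka/Ks`: a list of two alignments).
#' @param statistic one of `"pi"`, `"K"`, `"pi_a/pi_s"`, `"Ka/Ks"`.
#' @param window_bp,step_bp window width and step in bp.
#' @return data.frame with `start`, `end`, `mid` (1-based), `value`, `flag`.
#' @export
sliding_window <- function(aln, statistic = c("pi", "K", "pi_a/pi_s", "Ka/Ks"),
                           window_bp = 50L, step_bp = 10L) {
  statistic <- match.arg(statistic)
  paird <- statistic %in% c("K", "Ka/Ks")
  L <- if (paird) aln_len(aln[[1]]) else aln_len(aln)
  if (window_bp > L) stop("window larger than alignment")
  if (step_bp < 1) stop("step must be >= 1")
  starts <- seq(1L, max(1L, L - window_bp + 1L), by = step_bp)
  rows <- lapply(starts, function(st) {
    cols <- st:(min(L, st + window_bp - 1L))
    val <- NA_real_; flag <- ""
    if (statistic == "pi") {
      val <- nucleotide_diversity(aln_subset(aln, j = cols))$pi
    } else if (statistic == "K") {
      val <- jc_divergence(aln_subset(aln[[1]], j = cols),
                           aln_subset(aln[[2]], j = cols))$K_JC
    } else {
      # codon-aware ratios: restrict to codons fully inside the window
      if (statistic == "pi_a/pi_s") {
        ng <- nei_gojobori_within(codon_restrict(aln, cols))
        num <- ng$pi_a; den <- ng$pi_s
      } else {
        ng <- nei_gojobori_between(codon_restrict(aln[[1]], cols),
                                   codon_restrict(aln[[2]], cols))
        num <- ng$Ka; den <- ng$Ks
      }
      if (is.na(den) || den == 0) { flag <- "zero_denominator"; val <- NA_real_ }
      else val <- num / den
    }
    data.frame(start = st, end = min(L, st + window_bp - 1L),
               mid = st + (window_bp - 1) / 2, value = val, flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# subset an alignment to the codons fully contained in cols, preserving frame
codon_restrict <- function(aln, cols) {
  off <- aln$offset
  cidx <- unique((cols[cols > off] - 1 - off) %/% 3)
  keep <- unlist(lapply(cidx, function(ci) {
    cs <- off + ci * 3 + 1
    if (cs >= min(cols) && cs + 2 <= max(cols) && cs + 2 <= aln_len(aln)) cs:(cs + 2)
  }))
  if (is.null(keep) || !length(keep)) keep <- integer(0)
  out <- aln_subset(aln, j = keep)
  out$offset <- 0L
  out
}
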