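# Four-gamete machinery: compatibility checking, Hudson-Kaplan Rm, and the
# greedy infinite-sites filter used before coalescent-likelihood fitting.

# 0/1 encoding of biallelic segregating sites; NA for gap/N/other states.
# Returns matrix n x S with attribute "pos" (1-based column in aln).
biallelic_matrix <- function(aln, min_minor = 1L) {
  st <- segregating_sites(aln, classify = FALSE)
  st <- st[st$biallelic & st$minor_count >= min_minor, , drop = FALSE]
  s <- aln$seqs
  if (nrow(st) == 0) {
    m <- matrix(integer(0), nrow = n_seq(aln), ncol = 0)
    attr(m, "pos") <- integer(0)
    return(m)
  }
  m <- sapply(st$pos, function(j) {
    col <- s[, j]
    states <- strsplit(st$states[match(j, st$pos)], "/")[[1]]
    out <- rep(NA_integer_, length(col))
    out[col == states[1]] <- 0L   # major allele
    out[col == states[2]] <- 1L
    out
  })
  m <- matrix(m, nrow = n_seq(aln))
  attr(m, "pos") <- st$pos
  m
}

# TRUE if the pair of 0/1 columns shows all four gametes (pairwise-complete).
four_gametes <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  g <- unique(x[ok] * 2L + y[ok])
  length(g) == 4L
}

# All incompatible site pairs as a two-column matrix of indices into the
# biallelic matrix columns.
incompatible_pairs <- function(m) {
  S <- ncol(m)
  if (S < 2) return(matrix(integer(0), 0, 2))
  prs <- utils::combn(S, 2)
  bad <- apply(prs, 2, function(p) four_gametes(m[, p[1]], m[, p[2]]))
  t(prs[, bad, drop = FALSE])
}

#' Hudson-Kaplan minimum number of recombination events (Rm)
#'
#' Applies the four-gamete test to every pair of biallelic segregating sites
#' and reduces the incompatible intervals to a maximal set of non-overlapping
#' (disjoint, open-interval) ones; Rm is the size of that set.
#'
#' @param aln alignment (or a 0/1 site matrix with a `pos` attribute).
#' @return list with `Rm` and `intervals` (data.frame of 1-based bounding
#'   positions `left`, `right` of the retained disjoint intervals).
#' @export
hudson_kaplan_rm <- function(aln) {
  m <- if (inherits(aln, "aln")) biallelic_matrix(aln) else aln
  pos <- attr(m, "pos")
  inc <- incompatible_pairs(m)
  if (nrow(inc) == 0) {
    return(list(Rm = 0L, intervals = data.frame(left = integer(0), right = integer(0))))
  }
  iv <- cbind(pos[inc[, 1]], pos[inc[, 2]])
  iv <- iv[order(iv[, 2], iv[, 1]), , drop = FALSE]
  # greedy disjoint-interval selection on open intervals (left, right):
  # intervals overlap iff one's left bound is strictly inside the other;
  # sharing an endpoint site still means distinct events per Hudson & Kaplan.
  chosen <- matrix(integer(0), 0, 2)
  last_right <- -Inf
  for (k in seq_len(nrow(iv))) {
    if (iv[k, 1] >= last_right) {
      chosen <- rbind(chosen, iv[k, ])
      last_right <- iv[k, 2]
    }
  }
  list(Rm = nrow(chosen),
       intervals = data.frame(left = chosen[, 1], right = chosen[, 2]))
}

#' Test whether an alignment is infinite-sites compatible
#'
#' @param aln alignment.
#' @return TRUE when no pair of biallelic sites exhibits all four gametes and
#'   no site has more than two nucleotide states.
#' @export
is_infinite_sites <- function(aln) {
  st <- segregating_sites(aln, classify = FALSE)
  if (any(!st$biallelic)) return(FALSE)
  m <- biallelic_matrix(aln)
  nrow(incompatible_pairs(m)) == 0
}

#' Filter an alignment to infinite-sites (perfect phylogeny) compatibility
#'
#' Multiallelic sites are removed up front. Remaining four-gamete
#' incompatibilities are resolved greedily: at each step the site or the
#' sequence whose removal resolves the most remaining incompatible pairs is
#' removed, preferring site removal on ties (keeps sample size for the
#' coalescent likelihood). A sequence resolves a pair when it is the sole
#' carrier of one of the four gametes.
#'
#' @param aln alignment.
#' @return list with `aln` (filtered), `removed_sites` (1-based positions),
#'   `removed_sequences` (labels).
#' @export
infinite_sites_filter <- function(aln) {
  if (n_seq(aln) < 2) stop("need >=2 sequences")
  removed_sites <- integer(0)
  removed_seqs <- character(0)
  cur <- aln
  st <- segregating_sites(cur, classify = FALSE)
  multi <- st$pos[!st$biallelic]
  if (length(multi)) {
    removed_sites <- c(removed_sites, multi)
    keep <- setdiff(seq_len(aln_len(cur)), multi)
    cur <- blank_columns(cur, multi)
  }
  repeat {
    m <- biallelic_matrix(cur)
    inc <- incompatible_pairs(m)
    if (nrow(inc) == 0) break
    pos <- attr(m, "pos")
    site_gain <- tabulate(c(inc[, 1], inc[, 2]), nbins = ncol(m))
    # per-sequence gain: sole carrier of a gamete class within a bad pair
    seq_gain <- integer(n_seq(cur))
    for (k in seq_len(nrow(inc))) {
      x <- m[, inc[k, 1]]; y <- m[, inc[k, 2]]
      ok <- !is.na(x) & !is.na(y)
      g <- x * 2L + y
      tab <- table(g[ok])
      solo <- names(tab)[tab == 1L]
      if (length(solo)) {
        idx <- which(ok & g %in% as.integer(solo))
        seq_gain[idx] <- seq_gain[idx] + 1L
      }
    }
    if (max(site_gain) >= max(seq_gain) || n_seq(cur) <= 3L) {
      j <- which.max(site_gain)
      removed_sites <- c(removed_sites, pos[j])
      cur <- blank_columns(cur, pos[j])
    } else {
      i <- which.max(seq_gain)
      removed_seqs <- c(removed_seqs, rownames(cur$seqs)[i])
      cur <- aln_subset(cur, -i)
    }
  }
  list(aln = cur, removed_sites = sort(unique(removed_sites)),
       removed_sequences = removed_seqs)
}

# Replace columns by N so coordinates stay stable while the site no longer
# contributes polymorphism.
blank_columns <- function(aln, cols) {
  s <- aln$seqs
  s[, cols] <- "N"
  new_alignment(s, aln$meta, aln$offset)
}
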