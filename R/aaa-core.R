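#' @useDynLib poldiv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dpois fisher.test integrate nlminb optimize pchisq rbinom
#'   rexp rmultinom rpois runif setNames var
#' @importFrom utils combn read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Harmonic number a_n = sum_{i=1}^{n} 1/i
#'
#' The Watterson correction factor for a sample of n+1 alleles is `harmonic(n)`.
#'
#' @param n non-negative integer.
#' @return numeric scalar.
#' @export
harmonic <- function(n) {
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(0)
  sum(1 / seq_len(n))
}

harmonic2 <- function(n) {
  if (n == 0) return(0)
  sum(1 / seq_len(n)^2)
}

#' Tajima (1989) normalising constants
#'
#' Constants a1, a2, b1, b2, c1, c2, e1, e2 used by Tajima's D and by the
#' no-recombination variance of Watterson's theta.
#'
#' @param n number of sampled alleles (>= 2).
#' @return named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("need >= 2 sequences")
  a1 <- harmonic(n - 1)
  a2 <- harmonic2(n - 1)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

# Standard genetic code, codon -> one-letter amino acid ('*' = stop).
GENETIC_CODE_STD <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  # order: TTT TTC TTA TTG CTT ... is not what outer gives; build explicitly
  codons <- character(64)
  aas <- character(64)
  aa_tab <- paste0(
    "FFLLSSSSYY**CC*W", # TTT..TGG
    "LLLLPPPPHHQQRRRR", # CTT..CGG
    "IIIMTTTTNNKKSSRR", # ATT..AGG
    "VVVVAAAADDEEGGGG"  # GTT..GGG
  )
  k <- 0
  for (b1 in b) for (b2 in b) for (b3 in b) {
    k <- k + 1
    codons[k] <- paste0(b1, b2, b3)
  }
  aas <- strsplit(aa_tab, "")[[1]]
  setNames(aas, codons)
})

#' Translate a codon to a one-letter amino acid
#'
#' @param codon character vector of 3-letter codons (standard code).
#' @return character vector; `"*"` for stop, `NA` for codons with non-ACGT bases.
#' @export
translate_codon <- function(codon) {
  out <- GENETIC_CODE_STD[toupper(codon)]
  unname(out)
}

# Split a vector of equal-length sequences (character matrix rows) into codons.
codon_matrix <- function(seq_mat, offset = 0L) {
  L <- ncol(seq_mat) - offset
  if (L %% 3 != 0) stop("alignment length minus frame offset not divisible by 3")
  n_codon <- L / 3
  starts <- offset + 3 * (seq_len(n_codon) - 1) + 1
  list(starts = starts, n_codon = n_codon)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}
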