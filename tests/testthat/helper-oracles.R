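# Independent oracles: deliberately separate implementations (brute force,
# enumeration, or a second coalescent simulator) used to freeze expected
# values. None of these call the package code paths they check.

# brute-force segregating-site count: columns with >=2 distinct ACGT states
oracle_S <- function(seq_mat) {
  sum(apply(seq_mat, 2, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2
  }))
}

# brute-force per-site pi: average over sites of 2*sum_{i<j} delta / (n(n-1))
oracle_pi <- function(seq_mat) {
  n <- nrow(seq_mat)
  tot <- 0
  for (j in seq_len(ncol(seq_mat))) {
    col <- seq_mat[, j]
    ok <- which(col %in% c("A", "C", "G", "T"))
    if (length(ok) < 2) next
    d <- 0
    for (a in ok) for (b in ok) if (a < b && col[a] != col[b]) d <- d + 1
    tot <- tot + d / choose(n, 2)
  }
  tot / ncol(seq_mat)
}

# exhaustive two-tailed Fisher p for a 2x2 table by hypergeometric enumeration
oracle_fisher2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exhaustive maximal set of pairwise-disjoint open intervals (Rm oracle)
oracle_rm <- function(iv) {
  if (nrow(iv) == 0) return(0L)
  best <- 0L
  nset <- nrow(iv)
  for (mask in 0:(2^nset - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(nset) - 1)) > 0)
    if (length(idx) <= best) next
    ok <- TRUE
    if (length(idx) > 1) {
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (a < b) {
          i1 <- iv[idx[a], ]; i2 <- iv[idx[b], ]
          if (max(i1[1], i2[1]) < min(i1[2], i2[2])) ok <- FALSE
        }
      }
    }
    if (ok) best <- length(idx)
  }
  best
}

# brute-force four-gamete compatibility scan on a character alignment matrix
oracle_is_compatible <- function(seq_mat) {
  L <- ncol(seq_mat)
  cols <- lapply(seq_len(L), function(j) seq_mat[, j])
  bial <- list()
  for (j in seq_len(L)) {
    col <- cols[[j]]
    st <- unique(col[col %in% c("A", "C", "G", "T")])
    if (length(st) > 2) return(FALSE)
    if (length(st) == 2) bial[[length(bial) + 1]] <- list(j = j, st = st)
  }
  if (length(bial) < 2) return(TRUE)
  for (a in seq_along(bial)) for (b in seq_along(bial)) {
    if (a < b) {
      x <- cols[[bial[[a]]$j]]; y <- cols[[bial[[b]]$j]]
      ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
      if (length(unique(paste(x[ok], y[ok]))) == 4) return(FALSE)
    }
  }
  TRUE
}

# second, independent constant-size coalescent simulator (vector of n-1
# inter-coalescence epochs; returns per-class branch lengths and tree stats)
oracle_coal <- function(n) {
  # times via inverse-CDF on uniforms rather than rexp, merging by index walk
  k <- n
  ttot <- 0
  tm <- 0
  while (k > 1) {
    dt <- -log(runif(1)) / (k * (k - 1) / 2)
    tm <- tm + dt
    ttot <- ttot + k * dt
    k <- k - 1L
  }
  list(tmrca = tm, total = ttot)
}

# per-class branch lengths under constant size, independent implementation
oracle_class_lengths <- function(n) {
  k <- n
  sizes <- rep(1L, n)
  out <- numeric(n - 1)
  while (k > 1) {
    dt <- -log(runif(1)) / (k * (k - 1) / 2)
    for (i in seq_len(k)) out[sizes[i]] <- out[sizes[i]] + dt
    pick <- sample.int(k, 2)
    sizes[min(pick)] <- sizes[pick[1]] + sizes[pick[2]]
    sizes[max(pick)] <- sizes[k]
    k <- k - 1L
  }
  out
}

# independent Monte-Carlo constant-size likelihood of a folded SFS
oracle_sfs_lnl_constant <- function(eta, n, theta_locus, M) {
  K <- n %/% 2
  lik <- numeric(M)
  for (j in seq_len(M)) {
    cl <- oracle_class_lengths(n)
    lf <- numeric(K)
    for (m in seq_len(K)) lf[m] <- cl[m] + if (m != n - m) cl[n - m] else 0
    lik[j] <- prod(dpois(eta, theta_locus / 2 * lf))
  }
  log(mean(lik))
}

# Tajima's D from first principles on a 0/1 mutation description
oracle_tajima_D <- function(n, S, k) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}
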