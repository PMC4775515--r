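# Multilocus maximum-likelihood HKA with per-locus selection coefficients
# (Wright & Charlesworth 2004 parameterization): the selection coefficient k
# multiplies the polymorphism expectation only, so k < 1 reads as a sweep
# (polymorphism deficit) and k > 1 as balancing selection (excess).

#' Build the per-locus data table for the ML-HKA test
#'
#' @param loci named list; each element a list with the focal-species
#'   alignment `poly` and the two-group divergence pair `div` (list of two
#'   alignments), or precomputed counts `S`, `D`, `L`, `n`.
#' @param c_i inheritance scalars (1 nuclear, 0.25 mtDNA), recycled.
#' @param use_filtered apply [infinite_sites_filter()] before counting S?
#' @return data.frame with columns `locus`, `S`, `D`, `L`, `n`, `c`.
#' @export
hka_data <- function(loci, c_i = 1, use_filtered = FALSE) {
  c_i <- rep(c_i, length.out = length(loci))
  rows <- lapply(seq_along(loci), function(i) {
    x <- loci[[i]]
    if (!is.null(x$S)) {
      data.frame(locus = names(loci)[i] %||% paste0("locus", i),
                 S = x$S, D = x$D, L = x$L, n = x$n, c = c_i[i])
    } else {
      a <- x$poly
      if (use_filtered) a <- infinite_sites_filter(a)$aln
      S <- attr(segregating_sites(a, classify = FALSE), "S")
      D <- jc_divergence(x$div[[1]], x$div[[2]])$K_raw * aln_len(x$div[[1]])
      data.frame(locus = names(loci)[i] %||% paste0("locus", i),
                 S = S, D = D, L = aln_len(a), n = n_seq(a), c = c_i[i])
    }
  })
  do.call(rbind, rows)
}

# continuous Poisson log-density (divergence counts may be non-integer means)
dpois_cont <- function(x, lambda) x * log(lambda) - lambda - lgamma(x + 1)

# Tavare (1984) sampling distribution of the number of segregating sites
# under the constant-size coalescent: includes genealogical variance, unlike
# the Poisson approximation.
dS_coalescent <- function(S, n, lambda, log = TRUE) {
  if (lambda < 1e-10) {
    out <- if (S == 0) 0 else -Inf
    return(if (log) out else exp(out))
  }
  i <- seq_len(n - 1)
  terms <- (-1)^(i - 1) * choose(n - 1, i) * (i / (lambda + i)) *
    (lambda / (lambda + i))^S
  p <- max(sum(terms), 1e-300)
  if (log) log(p) else p
}

# divergence marginal: D | t ~ Pois(mu * (T + t)), t ~ Exp(1) the ancestral
# pairwise coalescent time; continuous in D, integrated by Gauss-Laguerre.
GL15 <- local({
  # nodes/weights of 15-point Gauss-Laguerre quadrature for int_0^inf f(t)e^-t
  n <- 15
  j <- 1:(n - 1)
  a <- 2 * (1:n) - 1
  J <- diag(a)
  J[cbind(j, j + 1)] <- j
  J[cbind(j + 1, j)] <- j
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = e$vectors[1, ]^2)
})

#' HKA log-likelihood
#'
#' Expected polymorphism is `k_i c_i theta_i L_i a_{n_i-1}` and expected
#' divergence `c_i theta_i L_i (T + div_c)`, with theta per site, T the
#' species divergence in units of 2N generations and `div_c` the
#' ancestral-polymorphism term (default 1). With `marginal = "poisson"` the
#' log-likelihood is the sum of Poisson log-densities at those means; the
#' default `"coalescent"` marginal keeps the same means but adds the
#' genealogical variance (Tavare's distribution of S; divergence mixed over
#' the ancestral pairwise coalescent time), which keeps the LRT near its
#' nominal size.
#'
#' @param data data.frame from [hka_data()].
#' @param theta per-locus per-site theta (> 0).
#' @param T_div divergence time parameter (> 0).
#' @param k per-locus selection coefficients (default all 1).
#' @param div_c ancestral-polymorphism constant added to T.
#' @param marginal `"coalescent"` (default) integrates the genealogical
#'   variance into both terms — Tavare's exact distribution of S and an
#'   Exp(1)-mixed Poisson for D — which keeps the LRT close to its nominal
#'   size; `"poisson"` is the naive fixed-genealogy approximation (liberal).
#' @return log-likelihood (scalar).
#' @export
hka_loglik <- function(data, theta, T_div, k = rep(1, nrow(data)), div_c = 1,
                       marginal = c("coalescent", "poisson")) {
  marginal <- match.arg(marginal)
  stopifnot(length(theta) == nrow(data), length(k) == nrow(data))
  if (any(theta <= 0) || T_div <= 0 || any(k <= 0)) stop("non-positive rate")
  a1 <- vapply(data$n, function(n) harmonic(n - 1), numeric(1))
  mu <- data$c * theta * data$L            # locus mutation intensity
  if (marginal == "poisson") {
    lam_S <- k * mu * a1
    lam_D <- mu * (T_div + div_c)
    return(sum(dpois_cont(data$S, lam_S)) + sum(dpois_cont(data$D, lam_D)))
  }
  ll <- 0
  for (i in seq_len(nrow(data))) {
    ll <- ll + dS_coalescent(data$S[i], data$n[i], k[i] * mu[i]) +
      dD_coalescent_c(data$D[i], mu[i], T_div, div_c)
  }
  ll
}

dD_coalescent_c <- function(D, mu, T_div, div_c) {
  ll <- dpois_cont(D, mu * (T_div + div_c * GL15$x))
  m <- max(ll)
  log(max(sum(GL15$w * exp(ll - m)), 1e-300)) + m
}

#' Fit the multilocus ML-HKA model
#'
#' Maximizes [hka_loglik()] over the per-locus thetas, the divergence time T
#' and the selection coefficients of the loci in `free_k` (all other k fixed
#' at 1), by bounded quasi-Newton on log-scale parameters with `n_restarts`
#' jittered restarts; the best restart is kept and the LnL spread across
#' restarts is reported as a convergence diagnostic.
#'
#' @param data data.frame from [hka_data()].
#' @param free_k character vector of locus names (subset of `data$locus`)
#'   whose k is free; empty for the null (all-neutral) model.
#' @param div_c ancestral-polymorphism constant.
#' @param n_restarts independent optimizer restarts.
#' @param seed integer seed for restart jitter.
#' @return list of class `hka_fit`: `lnL`, `theta`, `T_div`, `k`, `free_k`,
#'   `n_free` (free parameter count), `lnL_spread`, `converged`, `data`.
#' @export
fit_mlhka <- function(data, free_k = character(0), div_c = 1,
                      n_restarts = 3, seed = 1,
                      marginal = c("coalescent", "poisson")) {
  marginal <- match.arg(marginal)
  stopifnot(all(free_k %in% data$locus))
  nl <- nrow(data)
  free_idx <- match(free_k, data$locus)
  a1 <- vapply(data$n, function(n) harmonic(n - 1), numeric(1))
  # moment starts
  th0 <- pmax(data$S / (data$c * data$L * a1), 1e-5)
  T0 <- max(mean(data$D / (data$c * th0 * data$L)) - div_c, 0.05)
  obj <- function(par) {
    theta <- exp(par[1:nl])
    T_div <- exp(par[nl + 1])
    k <- rep(1, nl)
    if (length(free_idx)) k[free_idx] <- exp(par[nl + 1 + seq_along(free_idx)])
    -hka_loglik(data, theta, T_div, k, div_c, marginal)
  }
  p0 <- c(log(th0), log(T0), rep(0, length(free_idx)))
  set.seed(seed)
  best <- NULL; lnls <- numeric(0)
  for (r in seq_len(n_restarts)) {
    start <- p0 + if (r == 1) 0 else stats::rnorm(length(p0), 0, 0.5)
    fit <- tryCatch(
      stats::nlminb(start, obj, lower = rep(log(1e-8), length(p0)),
                    upper = rep(log(1e4), length(p0))),
      error = function(e) NULL)
    if (is.null(fit)) next
    lnls <- c(lnls, -fit$objective)
    if (is.null(best) || -fit$objective > -best$objective) best <- fit
  }
  if (is.null(best)) stop("all optimizer restarts failed")
  theta <- exp(best$par[1:nl])
  k <- rep(1, nl)
  if (length(free_idx)) k[free_idx] <- exp(best$par[nl + 1 + seq_along(free_idx)])
  spread <- if (length(lnls) > 1) diff(range(lnls)) else 0
  structure(list(lnL = -best$objective, theta = setNames(theta, data$locus),
                 T_div = exp(best$par[nl + 1]),
                 k = setNames(k, data$locus), free_k = free_k,
                 n_free = nl + 1 + length(free_idx),
                 lnL_spread = spread, converged = spread < 0.01,
                 data = data, div_c = div_c, marginal = marginal),
            class = "hka_fit")
}

#' @export
print.hka_fit <- function(x, ...) {
  cat(sprintf("<hka_fit> LnL = %.3f, T = %.3f; free k: %s\n", x$lnL, x$T_div,
              if (length(x$free_k)) paste(x$free_k, collapse = ", ") else "(none)"))
  print(round(rbind(theta = x$theta, k = x$k), 4))
  invisible(x)
}

#' Likelihood ratio test between nested fits
#'
#' @param null,alt fitted models with `lnL` and `n_free` fields (the null must
#'   be nested in the alternative).
#' @param tol tolerance on negative statistics before declaring an
#'   optimization failure.
#' @return list with `lnL_null`, `lnL_alt`, `statistic`, `df`, `p`.
#' @export
lrt <- function(null, alt, tol = 1e-4) {
  stat <- 2 * (alt$lnL - null$lnL)
  if (stat < -tol) stop("optimization failure: alternative LnL below null")
  stat <- max(stat, 0)
  df <- alt$n_free - null$n_free
  if (df < 0) stop("alternative has fewer free parameters than null")
  p <- if (df == 0) as.numeric(stat <= 0) else stats::pchisq(stat, df, lower.tail = FALSE)
  list(lnL_null = null$lnL, lnL_alt = alt$lnL, statistic = stat, df = df, p = p)
}
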