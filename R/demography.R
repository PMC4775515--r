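# Three-model coalescent-likelihood comparison (constant size / shared
# bottleneck / per-locus sweep). The sweep is modeled as a locus-specific
# instantaneous coalescent contraction (T_i, S_i); a bottleneck is the same
# event shared by all loci. The likelihood is a Monte-Carlo mixture over
# genealogies of the folded site-frequency-spectrum probability, which keeps
# tree-shape information while staying tractable.

fold_lengths <- function(unfolded) {
  n <- ncol(unfolded) + 1L
  K <- n %/% 2L
  out <- matrix(0, nrow(unfolded), K)
  for (m in seq_len(K)) {
    out[, m] <- unfolded[, m] + if (m != n - m) unfolded[, n - m] else 0
  }
  out
}

#' Observed folded site frequency spectrum
#'
#' Counts of biallelic segregating sites by minor-allele count (1..n/2);
#' multiallelic sites are dropped (the infinite-sites filter removes them
#' anyway before likelihood work).
#'
#' @param aln alignment.
#' @return integer vector of length `floor(n/2)`.
#' @export
folded_sfs <- function(aln) {
  n <- n_seq(aln)
  m <- biallelic_matrix(aln)
  K <- n %/% 2L
  eta <- integer(K)
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    cnt <- min(sum(x == 1L, na.rm = TRUE), sum(x == 0L, na.rm = TRUE))
    if (cnt >= 1) eta[min(cnt, K)] <- eta[min(cnt, K)] + 1L
  }
  eta
}

# MC likelihood of a folded SFS at locus-level theta given class lengths
sfs_loglik <- function(folded, eta, theta_locus) {
  ll <- sfs_loglik_terms(folded, as.numeric(eta), theta_locus / 2)
  const <- sum(lgamma(eta + 1))
  if (!any(is.finite(ll))) return(list(lnL = -Inf, mc_se = NA_real_))
  lnL <- log_mean_exp(ll) - const
  # delta-method MC standard error of the log of the weight mean
  ew <- exp(ll - max(ll[is.finite(ll)]))
  se <- stats::sd(ew) / (mean(ew) * sqrt(length(ew)))
  list(lnL = lnL, mc_se = se)
}

#' Coalescent Monte-Carlo log-likelihood of a contraction model
#'
#' Estimates the likelihood of the observed folded site frequency spectrum of
#' an infinite-sites-compatible alignment under a coalescent in which, at time
#' `T_event` (units of 2N generations) in the past, coalescent intensity is
#' instantaneously boosted by `S_event` (extra coalescent time compressed into
#' the event). Mutations are Poisson with rate theta/2 per lineage per unit
#' time. `S_event = 0` is the constant-size model.
#'
#' @param aln alignment (should pass [infinite_sites_filter()]; n >= 3).
#' @param theta locus-level theta (4N mu summed over sites).
#' @param T_event,S_event event time and strength (>= 0).
#' @param n_genealogy_samples Monte-Carlo genealogies (default 1e5).
#' @param seed integer seed.
#' @return list with `lnL` and `mc_se` (Monte-Carlo standard error).
#' @export
contraction_loglik <- function(aln, theta, T_event, S_event,
                               n_genealogy_samples = 1e5, seed = 1) {
  if (n_seq(aln) < 3) stop("degenerate data: need n >= 3 after filtering")
  if (theta <= 0 || T_event < 0 || S_event < 0) stop("parameters must be >= 0 (theta > 0)")
  eta <- folded_sfs(aln)
  set.seed(seed)
  lens <- fold_lengths(coal_class_lengths(n_seq(aln), T_event, S_event,
                                          as.integer(n_genealogy_samples)))
  sfs_loglik(lens, eta, theta)
}

# profile LnL over theta for one locus at one (T, S) grid point
profile_theta <- function(folded, eta, theta_max = 30) {
  f <- function(lth) {
    v <- sfs_loglik(folded, eta, exp(lth))$lnL
    if (!is.finite(v)) 1e10 else -v  # -Inf when no genealogy carries the SFS
  }
  if (sum(eta) == 0) {
    # monomorphic locus: likelihood maximized as theta -> 0; evaluate at floor
    op <- list(minimum = log(1e-4))
    return(list(theta = 1e-4, lnL = -f(log(1e-4))))
  }
  op <- stats::optimize(f, c(log(1e-4), log(theta_max)))
  list(theta = exp(op$minimum), lnL = -op$objective)
}

#' Fit the constant-size / bottleneck / sweep model trio to multilocus data
#'
#' M1 fits a per-locus theta under constant size; M2 adds one shared event
#' `(T_b, S_b)` across loci; M3 gives each locus its own `(T_i, S_i)`. The
#' event-likelihood surface is profiled over a (T, S) grid containing (0, 0);
#' genealogy seeds are tied to the grid point and locus so the three model
#' likelihoods are exactly nested (`LnL(M3) >= LnL(M2) >= LnL(M1)`). LRTs use
#' chi-square with df equal to parameter-count differences (2 for M2/M1,
#' 2 x n_loci for M3/M1); note that boundary parameters make the chi-square
#' approximation conservative-to-liberal.
#'
#' @param loci named list of alignments (each infinite-sites-filtered).
#' @param grid_T,grid_S grid values for the event time and strength (must
#'   include 0; defaults cover T, S in [0, 4]).
#' @param n_genealogy_samples Monte-Carlo genealogies per grid point.
#' @param theta_max upper bound of the per-locus theta search (default 30).
#' @param seed integer seed.
#' @param critical optional length-3 vector of empirical critical values for
#'   the LRT statistics (M2/M1, M3/M1, M3/M2), e.g. from
#'   [null_lrt_quantiles()]; the default `NULL` uses the chi-square
#'   reference, which is anticonservative for mutation-rich loci (see the
#'   methods vignette).
#' @return list of class `sweepbott_fit` with `M1`, `M2`, `M3` (each holding
#'   `lnL`, per-locus `lnL_locus`, `theta`, event parameters, `n_params`),
#'   `lrt` data.frame and `winner` by sequential LRT at alpha = 0.05.
#' @export
fit_three_models <- function(loci,
                             grid_T = c(0, 0.05, 0.1, 0.2, 0.45, 0.8, 1.5, 3),
                             grid_S = c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4),
                             n_genealogy_samples = 2000, theta_max = 30,
                             seed = 1, critical = NULL) {
  if (length(loci) < 2) stop("need >= 2 loci")
  etas <- lapply(loci, folded_sfs)
  ns <- vapply(loci, n_seq, 1L)
  names(etas) <- names(loci) %||% paste0("locus", seq_along(loci))
  fit_three_models_sfs(etas, ns, grid_T, grid_S, n_genealogy_samples,
                       theta_max, seed, critical)
}

# core on folded SFS vectors (etas: named list; ns: sample sizes)
fit_three_models_sfs <- function(etas, ns,
                                 grid_T = c(0, 0.05, 0.1, 0.2, 0.45, 0.8, 1.5, 3),
                                 grid_S = c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4),
                                 n_genealogy_samples = 2000, theta_max = 30,
                                 seed = 1, critical = NULL) {
  stopifnot(0 %in% grid_T, 0 %in% grid_S)
  nl <- length(etas)
  lnames <- names(etas) %||% paste0("locus", seq_len(nl))
  grid <- expand.grid(T = grid_T, S = grid_S)
  # profile LnL: loci x grid points (theta optimized per locus per point).
  # Common random numbers: one genealogy set per locus is remapped through
  # every (T, S), so the surfaces share Monte-Carlo noise and the three model
  # maxima are exactly nested without grid-max selection bias.
  prof <- matrix(NA_real_, nl, nrow(grid))
  theta_hat <- matrix(NA_real_, nl, nrow(grid))
  for (l in seq_len(nl)) {
    set.seed(seed + l)
    lens_list <- coal_grid_class_lengths(ns[l], grid$T, grid$S,
                                         as.integer(n_genealogy_samples))
    for (g in seq_len(nrow(grid))) {
      pr <- profile_theta(fold_lengths(lens_list[[g]]), etas[[l]], theta_max)
      prof[l, g] <- pr$lnL
      theta_hat[l, g] <- pr$theta
    }
  }
  g0 <- which(grid$T == 0 & grid$S == 0)[1]
  M1 <- list(lnL = sum(prof[, g0]), lnL_locus = setNames(prof[, g0], lnames),
             theta = setNames(theta_hat[, g0], lnames),
             n_params = nl, model = "M1")
  tot <- colSums(prof)
  g2 <- which.max(tot)
  M2 <- list(lnL = tot[g2], lnL_locus = setNames(prof[, g2], lnames),
             theta = setNames(theta_hat[, g2], lnames),
             T_b = grid$T[g2], S_b = grid$S[g2],
             n_params = nl + 2, model = "M2")
  g3 <- apply(prof, 1, which.max)
  M3 <- list(lnL = sum(prof[cbind(seq_len(nl), g3)]),
             lnL_locus = setNames(prof[cbind(seq_len(nl), g3)], lnames),
             theta = setNames(theta_hat[cbind(seq_len(nl), g3)], lnames),
             T_i = setNames(grid$T[g3], lnames),
             S_i = setNames(grid$S[g3], lnames),
             n_params = 3 * nl, model = "M3")
  lrt_row <- function(a, b) {
    stat <- max(0, 2 * (b$lnL - a$lnL))
    df <- b$n_params - a$n_params
    data.frame(test = paste0(b$model, "/", a$model), statistic = stat, df = df,
               p = stats::pchisq(stat, df, lower.tail = FALSE))
  }
  lrts <- rbind(lrt_row(M1, M2), lrt_row(M1, M3), lrt_row(M2, M3))
  # decision rule: an event model must beat M1; then M3 wins only if it
  # significantly improves on M2 (or M2 itself never beat M1)
  alpha <- 0.05
  sig <- if (is.null(critical)) lrts$p < alpha else lrts$statistic > critical
  winner <- "M1"
  if (sig[1] || sig[2]) {
    winner <- if (sig[3] || !sig[1]) "M3" else "M2"
  }
  structure(list(M1 = M1, M2 = M2, M3 = M3, lrt = lrts, winner = winner,
                 grid = grid, seed = seed,
                 n_genealogy_samples = n_genealogy_samples),
            class = "sweepbott_fit")
}

#' Empirical null quantiles for the three-model LRT statistics
#'
#' Simulates `B` neutral multilocus datasets (constant size, the given
#' per-locus sample sizes and locus-level thetas), runs the same grid-profile
#' fit as [fit_three_models()] on each, and returns the upper quantiles of
#' the three LRT statistics (M2/M1, M3/M1, M3/M2). The chi-square reference
#' is anticonservative for this Monte-Carlo profile likelihood, especially at
#' mutation-rich loci; these empirical critical values restore the nominal
#' test size (parametric-bootstrap calibration, as coalescent LRT software
#' traditionally recommends).
#'
#' @param ns integer vector of per-locus sample sizes.
#' @param theta_locus locus-level thetas (4N mu summed over sites); in
#'   practice the M1 estimates from the data.
#' @param B null replicates (default 100).
#' @param prob quantile level (default 0.95).
#' @param n_genealogy_samples,grid_T,grid_S,theta_max,seed as in
#'   [fit_three_models()] — use the same values you will fit the data with.
#' @return list with `critical` (length-3 vector) and `stats` (B x 3 matrix).
#' @export
null_lrt_quantiles <- function(ns, theta_locus, B = 100, prob = 0.95,
                               n_genealogy_samples = 2000,
                               grid_T = c(0, 0.05, 0.1, 0.2, 0.45, 0.8, 1.5, 3),
                               grid_S = c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4),
                               theta_max = 30, seed = 1) {
  nl <- length(ns)
  theta_locus <- rep(theta_locus, length.out = nl)
  stats <- matrix(NA_real_, B, 3)
  for (b in seq_len(B)) {
    set.seed(seed + 7919L * b)
    etas <- lapply(seq_len(nl), function(l) {
      lens <- fold_lengths(coal_class_lengths(ns[l], 0, 0, 1L))
      stats::rpois(length(lens), theta_locus[l] / 2 * lens[1, ])
    })
    names(etas) <- paste0("locus", seq_len(nl))
    ft <- fit_three_models_sfs(etas, ns, grid_T, grid_S, n_genealogy_samples,
                               theta_max, seed = seed + 31L * b)
    stats[b, ] <- ft$lrt$statistic
  }
  list(critical = apply(stats, 2, stats::quantile, probs = prob, names = FALSE),
       stats = stats)
}

#' @export
print.sweepbott_fit <- function(x, ...) {
  cat(sprintf("<sweepbott_fit> LnL: M1 %.2f | M2 %.2f (T=%.2f, S=%.2f) | M3 %.2f; winner %s\n",
              x$M1$lnL, x$M2$lnL, x$M2$T_b, x$M2$S_b, x$M3$lnL, x$winner))
  print(x$lrt, row.names = FALSE)
  invisible(x)
}
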