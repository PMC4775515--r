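# Mismatch-distribution analysis: observed pairwise-difference spectra,
# constant-size and Rogers-Harpending sudden-expansion expectations,
# least-squares expansion fitting, R2 and raggedness, and expansion dating.

#' Observed mismatch distribution
#'
#' Normalized histogram of pairwise difference counts over all n(n-1)/2
#' sequence pairs (pairwise deletion of gap/N positions). Its mean equals the
#' mean pairwise difference count (pi times L on gap-free data).
#'
#' @param aln alignment with `n >= 2`.
#' @return numeric vector of relative frequencies, names `0..max`.
#' @export
mismatch_observed <- function(aln) {
  n <- n_seq(aln)
  if (n < 2) stop("need >=2 sequences")
  s <- aln$seqs
  d <- integer(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- c(d, pair_diff(s[i, ], s[j, ])[1])
  }
  tab <- tabulate(d + 1L, nbins = max(d) + 1L)
  setNames(tab / sum(tab), 0:max(d))
}

#' Expected mismatch distribution under constant population size
#'
#' `F(i) = theta^i / (1 + theta)^(i+1)` (geometric), truncated at `i_max` and
#' renormalized.
#'
#' @param theta locus-level theta (4N mu per locus, > 0).
#' @param i_max largest difference class.
#' @param renormalize divide by the retained mass? Default TRUE.
#' @return numeric vector over classes `0..i_max`.
#' @export
mismatch_expected_constant <- function(theta, i_max, renormalize = TRUE) {
  i <- 0:i_max
  f <- if (theta == 0) c(1, rep(0, i_max)) else
    exp(i * log(theta) - (i + 1) * log1p(theta))
  if (renormalize) f <- f / sum(f)
  setNames(f, i)
}

#' Expected mismatch distribution under sudden expansion
#'
#' Rogers-Harpending (1992) model: a population at (ancestral) `theta0` grew
#' instantaneously to `theta1` at mutational time `tau` before present. In
#' closed form, with `Fc(i; th) = th^i/(1+th)^(i+1)` the constant-size curve,
#' `F(i) = Fc(i; theta1) * pgamma((1 + 1/theta1) tau, i+1)
#'       + exp(-tau/theta1) * sum_j dpois(j, tau) Fc(i-j; theta0)`.
#' At `tau = 0` this reduces to the constant-size curve at the ancestral
#' `theta0`; for large `tau` and small `theta0` it is a Poisson-like wave
#' centred near `tau`.
#'
#' @param theta0 ancestral (pre-expansion) locus theta (>= 0).
#' @param theta1 current (post-expansion) locus theta (>= theta0).
#' @param tau expansion time in mutational units (2 u t, >= 0).
#' @param i_max largest difference class.
#' @param renormalize renormalize the truncated vector? Default TRUE.
#' @return numeric vector over classes `0..i_max`.
#' @export
mismatch_expected_expansion <- function(theta0, theta1, tau, i_max,
                                        renormalize = TRUE) {
  stopifnot(theta0 >= 0, theta1 >= theta0, tau >= 0)
  i <- 0:i_max
  fc <- function(th, ii) {
    if (th == 0) return(as.numeric(ii == 0))
    exp(ii * log(th) - (ii + 1) * log1p(th))  # log space: stable for large i
  }
  if (theta1 <= 0) {
    f <- fc(theta0, i)  # no current epoch distinct from the ancestral one
  } else {
    beta <- 1 + 1 / theta1
    recent <- fc(theta1, i) * stats::pgamma(beta * tau, shape = i + 1)
    wave <- vapply(i, function(k) {
      j <- 0:k
      sum(stats::dpois(j, tau) * fc(theta0, k - j))
    }, numeric(1))
    f <- recent + exp(-tau / theta1) * wave
  }
  if (renormalize) f <- f / sum(f)
  setNames(f, i)
}

#' Ramos-Onsins & Rozas (2002) R2 statistic
#'
#' `R2 = sqrt(mean((U_i - k/2)^2)) / S` with `U_i` the number of singleton
#' sites at which sequence i carries the minority allele and `k` the mean
#' pairwise difference count.
#'
#' @param aln alignment.
#' @return numeric scalar (NA when S = 0).
#' @export
r2_stat <- function(aln) {
  st <- segregating_sites(aln, classify = FALSE)
  S <- attr(st, "S")
  if (S == 0) return(NA_real_)
  n <- n_seq(aln)
  s <- aln$seqs
  U <- integer(n)
  for (jrow in which(st$singleton)) {
    j <- st$pos[jrow]
    col <- s[, j]
    tab <- table(col[col %in% DNA_BASES])
    rare <- names(tab)[tab == 1]
    for (rb in rare) U[col == rb] <- U[col == rb] + 1L
  }
  k <- nucleotide_diversity(aln)$mean_pairwise
  sqrt(mean((U - k / 2)^2)) / S
}

#' Harpending's raggedness of a mismatch spectrum
#'
#' `r = sum_i (x_i - x_{i-1})^2` over adjacent difference classes.
#'
#' @param spectrum relative-frequency vector over classes 0..d.
#' @return numeric scalar.
#' @export
raggedness <- function(spectrum) {
  if (length(spectrum) < 2) return(0)
  sum(diff(spectrum)^2)
}

#' Fit the sudden-expansion model to an observed mismatch spectrum
#'
#' Least-squares fit of `(theta0, theta1, tau)` to the observed relative
#' frequencies, with `theta1 >= theta0 >= 0` enforced by the
#' parameterization. Also reports the constant-size least-squares fit (single
#' theta, initialized at the spectrum mean) and the R2 and raggedness
#' statistics of the data.
#'
#' @param observed relative-frequency vector (e.g. [mismatch_observed()]).
#' @param aln optional alignment used for R2 (and for the spectrum when
#'   `observed` is missing).
#' @return list of class `mismatch_fit`: `tau`, `theta0`, `theta1`,
#'   `sse_expansion`, `theta_constant`, `sse_constant`, `expected_expansion`,
#'   `expected_constant`, `observed`, `R2`, `raggedness`, `converged`.
#' @export
fit_expansion <- function(observed = NULL, aln = NULL) {
  if (is.null(observed)) observed <- mismatch_observed(aln)
  obs <- as.numeric(observed)
  i_max <- length(obs) - 1L
  mu <- sum((0:i_max) * obs)
  # constant-size fit
  objc <- function(lth) sum((obs - mismatch_expected_constant(exp(lth), i_max))^2)
  fc <- stats::optimize(objc, c(log(1e-4), log(1e3)))
  theta_c <- exp(fc$minimum)
  # expansion fit: theta0 = exp(a), theta1 = theta0 + exp(b), tau = exp(ct)
  obje <- function(p) {
    th0 <- exp(p[1]); th1 <- th0 + exp(p[2]); tau <- exp(p[3])
    sum((obs - mismatch_expected_expansion(th0, th1, tau, i_max))^2)
  }
  starts <- list(c(log(max(mu, 1) / 10), log(max(mu, 1) * 10), log(max(mu, 0.5))),
                 c(log(0.1), log(50), log(max(mu, 0.5))),
                 c(log(max(mu, 1)), log(max(mu, 1)), log(1e-6)))
  best <- NULL
  for (p0 in starts) {
    ft <- tryCatch(stats::nlminb(p0, obje,
                                 lower = c(log(1e-6), log(1e-6), log(1e-8)),
                                 upper = c(log(1e3), log(1e4), log(200))),
                   error = function(e) NULL)
    if (!is.null(ft) && (is.null(best) || ft$objective < best$objective)) best <- ft
  }
  conv <- !is.null(best)
  if (!conv) {
    best <- list(par = c(log(mu + 1e-6), log(mu + 1e-6), log(1e-8)), objective = NA)
  }
  th0 <- exp(best$par[1]); th1 <- th0 + exp(best$par[2]); tau <- exp(best$par[3])
  if (tau < 1e-6) tau <- 0
  structure(list(
    tau = tau, theta0 = th0, theta1 = th1,
    sse_expansion = best$objective,
    theta_constant = theta_c, sse_constant = fc$objective,
    expected_expansion = mismatch_expected_expansion(th0, th1, max(tau, 0), i_max),
    expected_constant = mismatch_expected_constant(theta_c, i_max),
    observed = setNames(obs, 0:i_max),
    R2 = if (is.null(aln)) NA_real_ else r2_stat(aln),
    raggedness = raggedness(obs),
    converged = conv), class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf("<mismatch_fit> tau = %.3f, theta0 = %.3g, theta1 = %.3g (SSE %.4g vs constant %.4g)\n",
              x$tau, x$theta0, x$theta1, x$sse_expansion, x$sse_constant))
  cat(sprintf("  R2 = %s, raggedness = %.4g\n",
              format(x$R2, digits = 3), x$raggedness))
  invisible(x)
}

#' Date an expansion from tau
#'
#' With `rate` the pairwise divergence rate per site per million years (the
#' classic "2 percent per My" convention, i.e. both lineages combined),
#' `t = tau / (rate * L)` million years. The per-lineage convention is
#' obtained by doubling `rate`. A theta-ratio dating under exponential growth
#' `theta_t = theta_0 exp(-g t)` is exposed via `g`: the time for the
#' observed theta ratio is `log(theta1/theta0)/g` (in the units of g).
#'
#' @param tau expansion time in mutational units.
#' @param rate pairwise divergence rate per site per My (> 0).
#' @param L locus length in bp.
#' @param g optional exponential growth rate; when supplied together with
#'   `theta0`/`theta1` the theta-ratio time is also returned.
#' @param theta0,theta1 optional pre/post-expansion thetas for the g-based
#'   dating.
#' @return list with `t_years` (and `t_growth_units` when `g` given).
#' @export
date_expansion <- function(tau, rate, L, g = NULL, theta0 = NULL, theta1 = NULL) {
  if (rate <= 0) stop("rate must be > 0")
  out <- list(t_years = tau / (rate * L) * 1e6)
  if (!is.null(g) && !is.null(theta0) && !is.null(theta1) && theta0 > 0 && g > 0) {
    out$t_growth_units <- log(theta1 / theta0) / g
  }
  out
}
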