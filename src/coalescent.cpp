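#include <Rcpp.h>
using namespace Rcpp;

// Coalescent genealogies under a constant-size history with an optional
// instantaneous coalescent-intensity burst: at real time T (units of 2N
// generations, looking back), S units of extra coalescent time are compressed
// into the event. Times are generated on the "effective" intensity scale and
// mapped back to real time; coalescences whose effective time falls inside
// (T, T+S] happen at real time T.
//
// Uses R's RNG throughout, so set.seed() in R controls reproducibility.

static inline double real_time(double t_eff, double T, double S) {
  if (t_eff <= T) return t_eff;
  if (t_eff <= T + S) return T;
  return t_eff - S;
}

// Single-event sampler: n_reps x (n-1) matrix of total branch length (real
// time) subtending i = 1..n-1 leaves.
// [[Rcpp::export]]
NumericMatrix coal_class_lengths(int n, double T_event, double S_event,
                                 int n_reps) {
  if (n < 2) stop("n must be >= 2");
  if (T_event < 0 || S_event < 0) stop("T and S must be >= 0");
  NumericMatrix out(n_reps, n - 1);
  std::vector<int> sizes(n);
  for (int rep = 0; rep < n_reps; ++rep) {
    int k = n;
    for (int i = 0; i < n; ++i) sizes[i] = 1;
    double t_eff = 0.0, t_real_prev = 0.0;
    while (k > 1) {
      double rate = k * (k - 1) / 2.0;
      t_eff += R::exp_rand() / rate;
      double t_real = real_time(t_eff, T_event, S_event);
      double dt = t_real - t_real_prev;
      if (dt > 0) {
        for (int i = 0; i < k; ++i) out(rep, sizes[i] - 1) += dt;
      }
      int a = (int)(R::unif_rand() * k); if (a >= k) a = k - 1;
      int b = (int)(R::unif_rand() * (k - 1)); if (b >= k - 1) b = k - 2;
      if (b >= a) ++b;
      int lo = a < b ? a : b, hi = a < b ? b : a;
      sizes[lo] += sizes[hi];
      sizes[hi] = sizes[k - 1];
      --k;
      t_real_prev = t_real;
    }
  }
  return out;
}

// Common-random-number grid sampler: the SAME n_reps genealogies (effective
// inter-coalescence times + topology) are pushed through every (T, S) grid
// point, so profile-likelihood surfaces share their Monte-Carlo noise and
// model comparisons on the grid are exactly nested without max-selection
// bias. Returns a list (one element per grid point) of n_reps x (n-1)
// class-length matrices.
// [[Rcpp::export]]
List coal_grid_class_lengths(int n, NumericVector T_grid, NumericVector S_grid,
                             int n_reps) {
  if (n < 2) stop("n must be >= 2");
  int G = T_grid.size();
  if (S_grid.size() != G) stop("T and S grids must have equal length");
  List out(G);
  std::vector<NumericMatrix> mats(G);
  for (int g = 0; g < G; ++g) mats[g] = NumericMatrix(n_reps, n - 1);

  std::vector<double> teff(n - 1);
  // per-interval class counts: counts[i][c] = #lineages of size c+1 during
  // interval i (between coalescence i and i+1; interval 0 starts at time 0)
  std::vector< std::vector<int> > counts(n - 1, std::vector<int>(n - 1));
  std::vector<int> sizes(n);

  for (int rep = 0; rep < n_reps; ++rep) {
    int k = n;
    for (int i = 0; i < n; ++i) sizes[i] = 1;
    double t = 0.0;
    for (int ev = 0; ev < n - 1; ++ev) {
      std::fill(counts[ev].begin(), counts[ev].end(), 0);
      for (int i = 0; i < k; ++i) counts[ev][sizes[i] - 1]++;
      double rate = k * (k - 1) / 2.0;
      t += R::exp_rand() / rate;
      teff[ev] = t;
      int a = (int)(R::unif_rand() * k); if (a >= k) a = k - 1;
      int b = (int)(R::unif_rand() * (k - 1)); if (b >= k - 1) b = k - 2;
      if (b >= a) ++b;
      int lo = a < b ? a : b, hi = a < b ? b : a;
      sizes[lo] += sizes[hi];
      sizes[hi] = sizes[k - 1];
      --k;
    }
    for (int g = 0; g < G; ++g) {
      double T = T_grid[g], S = S_grid[g];
      double prev = 0.0;
      for (int ev = 0; ev < n - 1; ++ev) {
        double tr = real_time(teff[ev], T, S);
        double dt = tr - prev;
        if (dt > 0) {
          for (int c = 0; c < n - 1; ++c) {
            if (counts[ev][c]) mats[g](rep, c) += dt * counts[ev][c];
          }
        }
        prev = tr;
      }
    }
  }
  for (int g = 0; g < G; ++g) out[g] = mats[g];
  return out;
}

// Monte-Carlo log-likelihood terms for a folded SFS given precomputed folded
// class lengths: ll_j = sum_m eta_m*log(rate*Lf_mj) - rate*sum_m Lf_mj
// (the -sum(lgamma(eta+1)) constant is added in R). Zero-length classes with
// eta_m > 0 give -Inf for that genealogy.
// [[Rcpp::export]]
NumericVector sfs_loglik_terms(NumericMatrix folded_lengths,
                               NumericVector eta, double rate) {
  int M = folded_lengths.nrow(), K = folded_lengths.ncol();
  if (eta.size() != K) stop("eta length mismatch");
  NumericVector ll(M);
  for (int j = 0; j < M; ++j) {
    double acc = 0.0;
    bool dead = false;
    for (int m = 0; m < K; ++m) {
      double lam = rate * folded_lengths(j, m);
      if (eta[m] > 0) {
        if (lam <= 0) { dead = true; break; }
        acc += eta[m] * std::log(lam);
      }
      acc -= lam;
    }
    ll[j] = dead ? R_NegInf : acc;
  }
  return ll;
}
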