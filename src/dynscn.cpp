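// Core numerics for local Frechet regression of covariance matrices and
// weighted-network summaries.  Everything here is deterministic given its
// arguments; randomized pieces (multilevel community detection) take an
// explicit seed.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <limits>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double WEIGHT_FLOOR = 1e-12;  // floor for sigma0^2 / Schur complement
static const double VAR_FLOOR    = 1e-12;  // floor for diagonal variances

// ---------------------------------------------------------------------------
// kernels
// ---------------------------------------------------------------------------

inline double kern(double u, int kernel) {
  if (kernel == 0) {                       // gaussian
    return 0.39894228040143268 * std::exp(-0.5 * u * u);
  }
  // epanechnikov
  double a = std::fabs(u);
  return (a < 1.0) ? 0.75 * (1.0 - u * u) : 0.0;
}

// ---------------------------------------------------------------------------
// local-linear weights, one covariate:
//   s_i(t, h) = K_h(T_i - t) [b2 - b1 (T_i - t)] / (b0 b2 - b1^2)
// with b_j = n^-1 sum K_h(T_i - t) (T_i - t)^j.  Mean of the weights is 1.
// ---------------------------------------------------------------------------

static vec weights_1d(const vec& T, double t, double h, int kernel, bool& ok) {
  const uword n = T.n_elem;
  vec d = T - t;
  vec Kh(n);
  for (uword i = 0; i < n; ++i) Kh[i] = kern(d[i] / h, kernel) / h;
  double b0 = mean(Kh);
  double b1 = mean(Kh % d);
  double b2 = mean(Kh % square(d));
  double sig0 = b0 * b2 - b1 * b1;
  if (!(sig0 > WEIGHT_FLOOR) || !std::isfinite(sig0)) {
    ok = false;
    return vec(n, fill::value(datum::nan));
  }
  ok = true;
  return (Kh % (b2 - b1 * d)) / sig0;
}

// ---------------------------------------------------------------------------
// local-linear weights, two covariates (product kernel):
//   s_i(x, h) = K_h(X_i - x) [1 - b1' b2^-1 (X_i - x)] / (b0 - b1' b2^-1 b1)
// ---------------------------------------------------------------------------

static vec weights_2d(const mat& X, const rowvec& x, const vec& h, int kernel,
                      bool& ok) {
  const uword n = X.n_rows;
  vec Kh(n);
  mat D(n, 2);
  for (uword i = 0; i < n; ++i) {
    double k = 1.0;
    for (uword dDim = 0; dDim < 2; ++dDim) {
      double u = (X(i, dDim) - x[dDim]) / h[dDim];
      D(i, dDim) = X(i, dDim) - x[dDim];
      k *= kern(u, kernel) / h[dDim];
    }
    Kh[i] = k;
  }
  double b0 = mean(Kh);
  vec b1(2, fill::zeros);
  mat b2(2, 2, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    b1 += Kh[i] * D.row(i).t();
    b2 += Kh[i] * (D.row(i).t() * D.row(i));
  }
  b1 /= (double)n;
  b2 /= (double)n;
  mat b2inv;
  bool inv_ok = inv_sympd(b2inv, b2);
  if (!inv_ok) inv_ok = inv(b2inv, b2);
  if (!inv_ok) { ok = false; return vec(n, fill::value(datum::nan)); }
  vec b2invb1 = b2inv * b1;
  double denom = b0 - dot(b1, b2invb1);
  if (!(denom > WEIGHT_FLOOR) || !std::isfinite(denom)) {
    ok = false;
    return vec(n, fill::value(datum::nan));
  }
  ok = true;
  vec w(n);
  for (uword i = 0; i < n; ++i)
    w[i] = Kh[i] * (1.0 - dot(b2invb1, D.row(i).t())) / denom;
  return w;
}

// ---------------------------------------------------------------------------
// Frechet covariance at a query point from the residual matrix.
// Sigma_hat = sum_i w_i r_i r_i' / sum_i w_i, then projection onto the PSD
// cone by eigenvalue clipping at 0 (nearest PSD matrix in Frobenius norm).
// ---------------------------------------------------------------------------

static bool psd_project(mat& S) {
  S = 0.5 * (S + S.t());
  vec eval;
  mat evec;
  if (!eig_sym(eval, evec, S)) return false;
  bool clipped = false;
  for (uword i = 0; i < eval.n_elem; ++i)
    if (eval[i] < 0.0) { eval[i] = 0.0; clipped = true; }
  if (clipped) {
    S = evec * diagmat(eval) * evec.t();
    S = 0.5 * (S + S.t());
  }
  return true;
}

static bool frechet_cov(const mat& resid, const vec& w, mat& S) {
  double sw = accu(w);
  if (!(sw > WEIGHT_FLOOR) || !std::isfinite(sw)) return false;
  S = resid.t() * (resid.each_col() % w) / sw;
  return psd_project(S);
}

// cov -> corr; false when a diagonal entry is at/below the variance floor
static bool cov_to_corr_inplace(mat& S) {
  const uword m = S.n_rows;
  vec d = S.diag();
  for (uword i = 0; i < m; ++i)
    if (!(d[i] > VAR_FLOOR) || !std::isfinite(d[i])) return false;
  vec s = 1.0 / sqrt(d);
  S = S % (s * s.t());
  for (uword i = 0; i < m; ++i) {
    for (uword j = 0; j < m; ++j) {
      if (S(i, j) > 1.0) S(i, j) = 1.0;
      if (S(i, j) < -1.0) S(i, j) = -1.0;
    }
    S(i, i) = 1.0;
  }
  return true;
}

// value-retaining thresholding with zero diagonal
static mat threshold_adj(const mat& R, double theta) {
  mat A = R;
  A.diag().zeros();
  for (uword i = 0; i < A.n_rows; ++i)
    for (uword j = 0; j < A.n_cols; ++j)
      if (i != j && A(i, j) < theta) A(i, j) = 0.0;
  return A;
}

// ---------------------------------------------------------------------------
// modularity of a weighted undirected network for a given node partition:
//   Q = (1/s) sum_ij (a_ij - d_i d_j / s) delta(m_i, m_j),  s = sum_ij a_ij
// ---------------------------------------------------------------------------

static double modularity_Q(const mat& A, const std::vector<int>& memb) {
  const uword m = A.n_rows;
  double s = accu(A);
  if (!(s > 0.0)) return 0.0;
  vec d = sum(A, 1);
  double Q = 0.0;
  for (uword i = 0; i < m; ++i)
    for (uword j = 0; j < m; ++j)
      if (memb[i] == memb[j]) Q += A(i, j) - d[i] * d[j] / s;
  return Q / s;
}

// all set partitions of m nodes (restricted growth strings), cached per m
// together with the list of same-module pairs (i < j) of each partition;
// feasible for m <= 8 (Bell(8) = 4140)
struct PartitionSet {
  std::vector<std::vector<int>> memb;        // membership strings
  std::vector<std::vector<int>> pairs;       // flat (i, j) same-pairs
};

static const PartitionSet& partition_cache(int m) {
  static std::vector<PartitionSet> cache(9);
  PartitionSet& ps = cache[m];
  if (!ps.memb.empty()) return ps;
  std::vector<int> a(m, 0);
  while (true) {
    ps.memb.push_back(a);
    std::vector<int> pr;
    for (int i = 0; i < m; ++i)
      for (int j = i + 1; j < m; ++j)
        if (a[i] == a[j]) { pr.push_back(i); pr.push_back(j); }
    ps.pairs.push_back(pr);
    int i = m - 1;
    while (i > 0) {
      int mx = 0;
      for (int j = 0; j < i; ++j) mx = std::max(mx, a[j]);
      if (a[i] <= mx) break;  // a[i] can be incremented
      --i;
    }
    if (i == 0) break;
    ++a[i];
    for (int j = i + 1; j < m; ++j) a[j] = 0;
  }
  return ps;
}

// exact maximum-modularity partition by enumeration
static double best_partition_exact(const mat& A, std::vector<int>& best) {
  const int m = (int)A.n_rows;
  double s = accu(A);
  best.assign(m, 0);
  if (!(s > 0.0)) return 0.0;
  vec d = sum(A, 1);
  mat B = A - (d * d.t()) / s;  // Q = accu(B % same)/s
  double diag_sum = trace(B);
  const PartitionSet& ps = partition_cache(m);
  double bestQ = -std::numeric_limits<double>::infinity();
  size_t besti = 0;
  for (size_t pi = 0; pi < ps.memb.size(); ++pi) {
    const std::vector<int>& pr = ps.pairs[pi];
    double acc = 0.0;
    for (size_t t = 0; t < pr.size(); t += 2) acc += B(pr[t], pr[t + 1]);
    double Q = (diag_sum + 2.0 * acc) / s;
    if (Q > bestQ + 1e-15) { bestQ = Q; besti = pi; }
  }
  best = ps.memb[besti];
  return bestQ;
}

// one level of multilevel (Louvain-style) local moving on a weighted graph
// with possible self-loops; returns achieved membership for this level
static bool louvain_local_moves(const mat& A, std::vector<int>& memb,
                                std::mt19937& rng) {
  const int m = (int)A.n_rows;
  double s = accu(A);
  vec k = sum(A, 1);
  // community totals of strengths and sizes
  std::vector<double> tot(m, 0.0);
  std::vector<int> csize(m, 0);
  for (int i = 0; i < m; ++i) { tot[memb[i]] += k[i]; ++csize[memb[i]]; }
  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;
  bool any_move = false, improved = true;
  while (improved) {
    improved = false;
    std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < m; ++oi) {
      int i = order[oi];
      int ci = memb[i];
      // links from i to each community (excluding self-edge)
      std::vector<double> kin(m, 0.0);
      for (int j = 0; j < m; ++j)
        if (j != i && A(i, j) > 0.0) kin[memb[j]] += A(i, j);
      tot[ci] -= k[i];
      --csize[ci];
      // gain of joining community c with i removed (relative, scaled by s):
      //   kin[c] - k_i * tot[c] / s
      double best_gain = kin[ci] - k[i] * tot[ci] / s;
      int best_c = ci;
      for (int c = 0; c < m; ++c) {
        if (c == ci || csize[c] == 0) continue;
        double g = kin[c] - k[i] * tot[c] / s;
        if (g > best_gain + 1e-14) { best_gain = g; best_c = c; }
      }
      if (best_gain < -1e-14) {
        // isolation (an empty community, gain 0) beats every candidate
        for (int c = 0; c < m; ++c)
          if (csize[c] == 0) { best_c = c; break; }
      }
      memb[i] = best_c;
      tot[best_c] += k[i];
      ++csize[best_c];
      if (best_c != ci) { improved = true; any_move = true; }
    }
  }
  return any_move;
}

static void relabel_contiguous(std::vector<int>& memb) {
  std::vector<int> map(memb.size(), -1);
  int next = 0;
  for (size_t i = 0; i < memb.size(); ++i) {
    if (map[memb[i]] < 0) map[memb[i]] = next++;
    memb[i] = map[memb[i]];
  }
}

static double louvain_once(const mat& A0, std::vector<int>& memb_out,
                           std::mt19937& rng) {
  const int m0 = (int)A0.n_rows;
  std::vector<int> node2final(m0);
  for (int i = 0; i < m0; ++i) node2final[i] = i;
  mat A = A0;
  std::vector<int> memb(m0);
  for (int i = 0; i < m0; ++i) memb[i] = i;

  while (true) {
    bool moved = louvain_local_moves(A, memb, rng);
    relabel_contiguous(memb);
    int K = 0;
    for (size_t i = 0; i < memb.size(); ++i) K = std::max(K, memb[i] + 1);
    // update mapping from original nodes to current communities
    for (int i = 0; i < m0; ++i) node2final[i] = memb[node2final[i]];
    if (!moved || K == (int)A.n_rows) break;
    // aggregate
    mat Anew(K, K, fill::zeros);
    for (uword i = 0; i < A.n_rows; ++i)
      for (uword j = 0; j < A.n_cols; ++j)
        Anew(memb[i], memb[j]) += A(i, j);
    A = Anew;
    memb.assign(K, 0);
    for (int i = 0; i < K; ++i) memb[i] = i;
  }
  memb_out = node2final;
  relabel_contiguous(memb_out);
  return modularity_Q(A0, memb_out);
}

// best partition: exact enumeration when m <= 8, multilevel heuristic with
// restarts otherwise
static double best_partition(const mat& A, std::vector<int>& memb,
                             unsigned int seed, int restarts) {
  const int m = (int)A.n_rows;
  if (accu(A) <= 0.0) { memb.assign(m, 0); return 0.0; }
  if (m <= 8) return best_partition_exact(A, memb);
  std::mt19937 rng(seed);
  double bestQ = -std::numeric_limits<double>::infinity();
  std::vector<int> cur;
  for (int r = 0; r < restarts; ++r) {
    double Q = louvain_once(A, cur, rng);
    if (Q > bestQ) { bestQ = Q; memb = cur; }
  }
  return bestQ;
}

// ---------------------------------------------------------------------------
// global efficiency:
//   E = (1/m) sum_i [ sum_{j != i} 1/l_ij ] / (m - 1)
// l_ij = weighted shortest path length; disconnected pairs contribute 0.
// rule 0: edge length = edge weight (sum of weights along the path)
// rule 1: edge length = 1 / weight
// ---------------------------------------------------------------------------

static double global_eff(const mat& A, int rule) {
  const int m = (int)A.n_rows;
  const double INF = std::numeric_limits<double>::infinity();
  mat L(m, m);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j) {
      if (i == j) L(i, j) = 0.0;
      else if (A(i, j) > 0.0) L(i, j) = (rule == 0) ? A(i, j) : 1.0 / A(i, j);
      else L(i, j) = INF;
    }
  double total = 0.0;
  std::vector<double> dist(m);
  std::vector<bool> done(m);
  for (int src = 0; src < m; ++src) {       // Dijkstra, dense O(m^2)
    for (int i = 0; i < m; ++i) { dist[i] = INF; done[i] = false; }
    dist[src] = 0.0;
    for (int it = 0; it < m; ++it) {
      int u = -1;
      double du = INF;
      for (int i = 0; i < m; ++i)
        if (!done[i] && dist[i] < du) { du = dist[i]; u = i; }
      if (u < 0) break;
      done[u] = true;
      for (int v = 0; v < m; ++v)
        if (!done[v] && L(u, v) < INF && du + L(u, v) < dist[v])
          dist[v] = du + L(u, v);
    }
    for (int j = 0; j < m; ++j)
      if (j != src && dist[j] < INF && dist[j] > 0.0) total += 1.0 / dist[j];
  }
  return total / ((double)m * (double)(m - 1));
}

// measure of a thresholded network; measure 0 = modularity (best partition),
// 1 = global efficiency
static double network_measure(const mat& A, int measure, int rule,
                              unsigned int seed, int restarts) {
  if (measure == 0) {
    std::vector<int> memb;
    return best_partition(A, memb, seed, restarts);
  }
  return global_eff(A, rule);
}

// deterministic per-cell seed mixing
inline unsigned int mix_seed(unsigned int base, unsigned int a, unsigned int b,
                             unsigned int c, unsigned int d) {
  unsigned int h = base;
  h = h * 2654435761u + a;
  h = h * 2246822519u + b;
  h = h * 3266489917u + c;
  h = h * 668265263u + d;
  h ^= h >> 13;
  return h;
}

// ===========================================================================
// exported endpoints
// ===========================================================================

// [[Rcpp::export]]
Rcpp::NumericVector cpp_local_weights_1d(Rcpp::NumericVector T, double t,
                                         double h, int kernel) {
  vec Tv(T.begin(), T.size());
  bool ok = false;
  vec w = weights_1d(Tv, t, h, kernel, ok);
  Rcpp::NumericVector out(w.begin(), w.end());
  out.attr("ok") = ok;
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_local_weights_2d(Rcpp::NumericMatrix X,
                                         Rcpp::NumericVector x,
                                         Rcpp::NumericVector h, int kernel) {
  mat Xm(X.begin(), X.nrow(), X.ncol(), false);
  rowvec xv(2);
  xv[0] = x[0]; xv[1] = x[1];
  vec hv(2);
  hv[0] = h[0]; hv[1] = h[1];
  bool ok = false;
  vec w = weights_2d(Xm, xv, hv, kernel, ok);
  Rcpp::NumericVector out(w.begin(), w.end());
  out.attr("ok") = ok;
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_nearest_psd(arma::mat S) {
  if (!psd_project(S)) Rcpp::stop("eigendecomposition failed");
  return S;
}

// Frechet covariance/correlation at one query point (one covariate).
// [[Rcpp::export]]
Rcpp::List cpp_frechet_corr_at(const arma::mat& resid,
                               const arma::vec& ages, double t, double h,
                               int kernel, bool want_corr) {
  bool ok = false;
  vec w = weights_1d(ages, t, h, kernel, ok);
  if (!ok)
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("reason") = "degenerate_weights");
  mat S;
  if (!frechet_cov(resid, w, S))
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("reason") = "zero_weight_sum");
  mat Sigma = S;
  if (want_corr && !cov_to_corr_inplace(S))
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("reason") = "zero_variance",
                              Rcpp::Named("cov") = Sigma);
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("cov") = Sigma,
                            Rcpp::Named("corr") = S,
                            Rcpp::Named("ess") = accu(abs(w)) /
                              (double)w.n_elem);
}

// Frechet covariance/correlation at one (age, score) query point.
// [[Rcpp::export]]
Rcpp::List cpp_frechet_corr_at2(const arma::mat& resid, const arma::mat& X,
                                const arma::vec& x, const arma::vec& h,
                                int kernel, bool want_corr) {
  rowvec xv = x.t();
  bool ok = false;
  vec w = weights_2d(X, xv, h, kernel, ok);
  if (!ok)
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("reason") = "degenerate_weights");
  mat S;
  if (!frechet_cov(resid, w, S))
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("reason") = "zero_weight_sum");
  mat Sigma = S;
  if (want_corr && !cov_to_corr_inplace(S))
    return Rcpp::List::create(Rcpp::Named("ok") = false,
                              Rcpp::Named("reason") = "zero_variance",
                              Rcpp::Named("cov") = Sigma);
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("cov") = Sigma,
                            Rcpp::Named("corr") = S,
                            Rcpp::Named("ess") = accu(abs(w)) /
                              (double)w.n_elem);
}

// [[Rcpp::export]]
Rcpp::List cpp_best_partition(const arma::mat& A, int seed, int restarts) {
  std::vector<int> memb;
  double Q = best_partition(A, memb, (unsigned int)seed, restarts);
  Rcpp::IntegerVector m(memb.size());
  for (size_t i = 0; i < memb.size(); ++i) m[i] = memb[i] + 1;
  return Rcpp::List::create(Rcpp::Named("membership") = m,
                            Rcpp::Named("modularity") = Q,
                            Rcpp::Named("exact") = (A.n_rows <= 8));
}

// [[Rcpp::export]]
Rcpp::List cpp_best_partition_multilevel(const arma::mat& A, int seed,
                                         int restarts) {
  std::vector<int> memb;
  double bestQ;
  if (accu(A) <= 0.0) {
    memb.assign(A.n_rows, 0);
    bestQ = 0.0;
  } else {
    std::mt19937 rng((unsigned int)seed);
    std::vector<int> cur;
    bestQ = -std::numeric_limits<double>::infinity();
    for (int r = 0; r < restarts; ++r) {
      double Q = louvain_once(A, cur, rng);
      if (Q > bestQ) { bestQ = Q; memb = cur; }
    }
  }
  Rcpp::IntegerVector m(memb.size());
  for (size_t i = 0; i < memb.size(); ++i) m[i] = memb[i] + 1;
  return Rcpp::List::create(Rcpp::Named("membership") = m,
                            Rcpp::Named("modularity") = bestQ,
                            Rcpp::Named("exact") = false);
}

// [[Rcpp::export]]
double cpp_modularity(const arma::mat& A, Rcpp::IntegerVector membership) {
  std::vector<int> memb(membership.size());
  for (int i = 0; i < membership.size(); ++i) memb[i] = membership[i];
  return modularity_Q(A, memb);
}

// [[Rcpp::export]]
double cpp_global_efficiency(const arma::mat& A, int rule) {
  return global_eff(A, rule);
}

// ---------------------------------------------------------------------------
// permutation engine, grouped analysis (one covariate: age).
//
// resid:  n x m residual matrix (pooled mean fit)
// ages:   n
// labels: n x P integer matrix of group assignments in 1..K; column 1 is the
//         observed assignment, the rest are permutations
// hk:     per-group bandwidths (length K)
// Returns a K x N x P cube of threshold-averaged measure values; cells that
// cannot be estimated are NaN (the whole permutation is then discarded on
// the R side).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::cube cpp_perm_group_curves(const arma::mat& resid, const arma::vec& ages,
                                 const arma::imat& labels, int K,
                                 const arma::vec& qages, const arma::vec& hk,
                                 int kernel, const arma::vec& thetas,
                                 int measure, int rule, int seed,
                                 int restarts) {
  const uword P = labels.n_cols, N = qages.n_elem, H = thetas.n_elem;
  cube out(K, N, P);
  out.fill(datum::nan);
  for (uword p = 0; p < P; ++p) {
    for (int k = 1; k <= K; ++k) {
      uvec idx = find(labels.col(p) == k);
      if (idx.n_elem < 2) continue;
      mat Rk = resid.rows(idx);
      vec Tk = ages(idx);
      for (uword j = 0; j < N; ++j) {
        bool ok = false;
        vec w = weights_1d(Tk, qages[j], hk[k - 1], kernel, ok);
        if (!ok) continue;
        mat S;
        if (!frechet_cov(Rk, w, S)) continue;
        if (!cov_to_corr_inplace(S)) continue;
        double acc = 0.0;
        for (uword hI = 0; hI < H; ++hI) {
          mat A = threshold_adj(S, thetas[hI]);
          unsigned int cs = mix_seed((unsigned int)seed, p, k, j, hI);
          acc += network_measure(A, measure, rule, cs, restarts);
        }
        out(k - 1, j, p) = acc / (double)H;
      }
    }
    if (p % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// permutation engine, bivariate analysis (age, cognitive score).
// elcs: n x P matrix; column 1 observed scores, the rest permutations.
// scores: K evaluation scores.  Returns K x N x P cube as above.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::cube cpp_perm_elc_curves(const arma::mat& resid, const arma::vec& ages,
                               const arma::mat& elcs, const arma::vec& qages,
                               const arma::vec& scores, double h_age,
                               double h_elc, int kernel,
                               const arma::vec& thetas, int measure, int rule,
                               int seed, int restarts) {
  const uword P = elcs.n_cols, N = qages.n_elem, H = thetas.n_elem,
              K = scores.n_elem, n = resid.n_rows;
  vec h(2);
  h[0] = h_age; h[1] = h_elc;
  cube out(K, N, P);
  out.fill(datum::nan);
  for (uword p = 0; p < P; ++p) {
    mat X(n, 2);
    X.col(0) = ages;
    X.col(1) = elcs.col(p);
    for (uword k = 0; k < K; ++k) {
      for (uword j = 0; j < N; ++j) {
        rowvec x(2);
        x[0] = qages[j]; x[1] = scores[k];
        bool ok = false;
        vec w = weights_2d(X, x, h, kernel, ok);
        if (!ok) continue;
        mat S;
        if (!frechet_cov(resid, w, S)) continue;
        if (!cov_to_corr_inplace(S)) continue;
        double acc = 0.0;
        for (uword hI = 0; hI < H; ++hI) {
          mat A = threshold_adj(S, thetas[hI]);
          unsigned int cs = mix_seed((unsigned int)seed, p, k, j, hI);
          acc += network_measure(A, measure, rule, cs, restarts);
        }
        out(k, j, p) = acc / (double)H;
      }
    }
    if (p % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
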