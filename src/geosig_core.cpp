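// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Lawson-Hanson active-set non-negative least squares:
//   minimize ||A x - b||_2 subject to x >= 0.
// A is channels x signatures (tall, small column count), b a spectrum.
// [[Rcpp::export]]
Rcpp::List nnls_cpp(const arma::mat& A, const arma::vec& b) {
  const uword n = A.n_cols;
  const double tol = 10.0 * datum::eps * norm(A, "fro") *
    static_cast<double>(std::max(A.n_rows, n));
  std::vector<bool> passive(n, false);
  vec x(n, fill::zeros);
  vec w = A.t() * (b - A * x);
  const int maxit = 30 * static_cast<int>(n) + 50;
  int outer = 0;
  while (true) {
    double wmax = -datum::inf;
    int t = -1;
    for (uword j = 0; j < n; ++j) {
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = static_cast<int>(j); }
    }
    if (t < 0 || wmax <= tol) break;
    passive[t] = true;
    // inner loop: restore feasibility of the passive-set LS solution
    int inner = 0;
    while (true) {
      std::vector<uword> pv;
      for (uword j = 0; j < n; ++j) if (passive[j]) pv.push_back(j);
      uvec pidx(pv.size());
      for (size_t i = 0; i < pv.size(); ++i) pidx(i) = pv[i];
      vec z = solve(A.cols(pidx), b);
      if (z.n_elem > 0 && z.min() > 0) {
        x.zeros();
        x(pidx) = z;
        break;
      }
      double alpha = datum::inf;
      for (uword i = 0; i < pidx.n_elem; ++i) {
        if (z(i) <= 0) {
          double xi = x(pidx(i));
          double a = xi / (xi - z(i));
          if (a < alpha) alpha = a;
        }
      }
      vec xp = x(pidx);
      xp += alpha * (z - xp);
      x.zeros();
      x(pidx) = xp;
      for (uword i = 0; i < pidx.n_elem; ++i) {
        if (x(pidx(i)) <= tol) { passive[pidx(i)] = false; x(pidx(i)) = 0.0; }
      }
      if (++inner > maxit) break;
    }
    w = A.t() * (b - A * x);
    if (++outer > maxit) break;
  }
  const double resid = norm(b - A * x, 2);
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("resid") = resid);
}

static double kl_divergence(const mat& V, const mat& WH, double eps) {
  // generalized KL: sum v*log(v/wh) - v + wh, with 0*log(0) = 0
  double d = 0.0;
  for (uword j = 0; j < V.n_cols; ++j) {
    for (uword i = 0; i < V.n_rows; ++i) {
      const double v = V(i, j);
      const double m = WH(i, j) + eps;
      if (v > 0) d += v * std::log(v / m) - v + m;
      else d += m;
    }
  }
  return d;
}

// Multiplicative-update NMF under the generalized Kullback-Leibler
// objective. W (channels x k) and H (k x samples) are the initial factors;
// iterates until the relative objective change drops below tol.
// [[Rcpp::export]]
Rcpp::List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      double tol, int max_iter, double eps,
                      bool trace = false) {
  mat WH = W * H;
  double prev = kl_divergence(V, WH, eps);
  std::vector<double> objs;
  if (trace) objs.push_back(prev);
  int it = 0;
  double cur = prev;
  for (it = 1; it <= max_iter; ++it) {
    // H update
    mat Q = V / (WH + eps);
    H %= (W.t() * Q);
    vec wc = sum(W, 0).t() + eps;
    H.each_col() /= wc;
    // W update
    WH = W * H;
    Q = V / (WH + eps);
    W %= (Q * H.t());
    vec hr = sum(H, 1) + eps;
    W.each_row() /= hr.t();
    WH = W * H;
    cur = kl_divergence(V, WH, eps);
    if (trace) objs.push_back(cur);
    const double denom = std::max(std::abs(prev), 1e-300);
    if (std::abs(prev - cur) / denom < tol) break;
    prev = cur;
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("objective") = cur,
    Rcpp::Named("iterations") = std::min(it, max_iter),
    Rcpp::Named("objective_trace") = objs);
}

// Exact minimum-cost one-to-one assignment (Hungarian algorithm with
// potentials, O(n^3)); returns, for each row, the 1-based assigned column.
// [[Rcpp::export]]
Rcpp::IntegerVector hungarian_cpp(const arma::mat& cost) {
  const int n = static_cast<int>(cost.n_rows);
  if (static_cast<int>(cost.n_cols) != n)
    Rcpp::stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      int j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (!used[j]) {
          const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      const int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  Rcpp::IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
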