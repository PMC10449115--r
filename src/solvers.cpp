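// Constrained least-squares primitives for the deconvolution stages.
//
// All three constrained problems reduce to nonnegative least squares:
//  - proportions:  min ||t - M p||^2, p >= 0, sum(p) = 1
//      handled by appending a heavily weighted row enforcing sum(p) = 1;
//  - profiles:     min ||t - P' m||^2, 0 <= m <= 1
//      handled by a slack variable s >= 0 with weighted rows m + s = 1;
//  - stage 2:      min ||x - P' m||^2, m >= 0  (plain NNLS).
// The penalty weight (1e6 on unit-scale data) perturbs solutions by
// O(w^-2), far below the tolerances used anywhere downstream.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double PENALTY_W = 1e6;

// Lawson-Hanson active-set NNLS: min ||A x - b||, x >= 0.
static vec nnls_core(const mat& A, const vec& b, int max_outer = 0) {
  const uword n = A.n_cols;
  if (max_outer <= 0) max_outer = 3 * static_cast<int>(n) + 30;
  std::vector<bool> passive(n, false);
  vec x(n, fill::zeros);
  vec w = A.t() * (b - A * x);
  const double tol = 10 * datum::eps * norm(A, "fro") * std::max(A.n_rows, n);

  int outer = 0;
  while (outer++ < max_outer) {
    // pick most violating coordinate in the active (zero) set
    int t = -1;
    double wmax = tol;
    for (uword j = 0; j < n; ++j)
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = static_cast<int>(j); }
    if (t < 0) break;
    passive[t] = true;

    for (;;) {
      uvec P(n);
      uword np = 0;
      for (uword j = 0; j < n; ++j) if (passive[j]) P(np++) = j;
      P.resize(np);
      vec z;
      bool ok = solve(z, A.cols(P), b, solve_opts::fast);
      if (!ok) z = pinv(A.cols(P)) * b;

      if (z.min() > 0) {
        x.zeros();
        x.elem(P) = z;
        break;
      }
      // step back along (x -> z) to the first bound, drop that coordinate
      double alpha = datum::inf;
      for (uword i = 0; i < np; ++i)
        if (z(i) <= 0) {
          double xi = x(P(i));
          double a = xi / (xi - z(i));
          if (a < alpha) alpha = a;
        }
      for (uword i = 0; i < np; ++i) x(P(i)) += alpha * (z(i) - x(P(i)));
      for (uword i = 0; i < np; ++i)
        if (x(P(i)) <= tol) { passive[P(i)] = false; x(P(i)) = 0; }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

// [[Rcpp::export(name = ".cppNNLS")]]
arma::vec cpp_nnls(const arma::mat& A, const arma::vec& b) {
  return nnls_core(A, b);
}

// Simplex-constrained LS for one sample column.
static vec simplex_ls(const mat& M, const vec& t) {
  const uword k = M.n_cols;
  mat A(M.n_rows + 1, k);
  A.rows(0, M.n_rows - 1) = M;
  A.row(M.n_rows).fill(PENALTY_W);
  vec b(M.n_rows + 1);
  b.subvec(0, M.n_rows - 1) = t;
  b(M.n_rows) = PENALTY_W;
  vec p = nnls_core(A, b);
  double s = accu(p);
  if (s > 0) p /= s; else p.fill(1.0 / k);
  return p;
}

// Box-constrained [0,1] LS for one gene row: variables (m, s), m + s = 1.
static vec box_ls(const mat& Pt, const vec& t) {
  const uword k = Pt.n_cols, n = Pt.n_rows;
  mat A(n + k, 2 * k, fill::zeros);
  A.submat(0, 0, n - 1, k - 1) = Pt;
  for (uword j = 0; j < k; ++j) {
    A(n + j, j) = PENALTY_W;
    A(n + j, k + j) = PENALTY_W;
  }
  vec b(n + k);
  b.subvec(0, n - 1) = t;
  b.subvec(n, n + k - 1).fill(PENALTY_W);
  vec z = nnls_core(A, b);
  vec m = clamp(z.subvec(0, k - 1), 0.0, 1.0);
  return m;
}

// [[Rcpp::export(name = ".cppSolveProportions")]]
arma::mat cpp_solve_proportions(const arma::mat& M, const arma::mat& T) {
  mat P(M.n_cols, T.n_cols);
  for (uword j = 0; j < T.n_cols; ++j) P.col(j) = simplex_ls(M, T.col(j));
  return P;
}

// [[Rcpp::export(name = ".cppSolveProfiles")]]
arma::mat cpp_solve_profiles(const arma::mat& P, const arma::mat& T) {
  // T genes x samples, P k x samples; returns genes x k
  mat Pt = P.t();
  mat M(T.n_rows, P.n_rows);
  for (uword g = 0; g < T.n_rows; ++g)
    M.row(g) = box_ls(Pt, T.row(g).t()).t();
  return M;
}

// [[Rcpp::export(name = ".cppSolveNonneg")]]
arma::mat cpp_solve_nonneg(const arma::mat& P, const arma::mat& X) {
  // per-gene plain NNLS: X genes x samples, P k x samples
  mat Pt = P.t();
  mat M(X.n_rows, P.n_rows);
  for (uword g = 0; g < X.n_rows; ++g)
    M.row(g) = nnls_core(Pt, X.row(g).t()).t();
  return M;
}

// Alternating minimization: profile step then proportion step per iteration.
// [[Rcpp::export(name = ".cppAlternate")]]
Rcpp::List cpp_alternate(const arma::mat& T, const arma::mat& M0,
                         int max_iter, double rss_tol) {
  mat M = M0;
  mat P = cpp_solve_proportions(M, T);
  std::vector<double> rss_traj;
  double rss_prev = datum::inf;
  bool converged = false;
  int it = 0;
  mat bestM = M, bestP = P;
  for (it = 1; it <= max_iter; ++it) {
    mat Mn = cpp_solve_profiles(P, T);
    mat Pn = cpp_solve_proportions(Mn, T);
    double rss = accu(square(T - Mn * Pn));
    if (rss > rss_prev) {  // numerically negligible uptick: keep previous
      converged = true;
      break;
    }
    M = Mn; P = Pn;
    rss_traj.push_back(rss);
    if (rss_prev - rss < rss_tol) { converged = true; rss_prev = rss; break; }
    rss_prev = rss;
  }
  return Rcpp::List::create(
      Rcpp::Named("M") = M, Rcpp::Named("P") = P,
      Rcpp::Named("rss") = rss_traj,
      Rcpp::Named("iterations") = static_cast<int>(rss_traj.size()),
      Rcpp::Named("converged") = converged);
}

// O(n^3) Hungarian algorithm (potentials formulation), minimizing cost.
// [[Rcpp::export(name = ".cppHungarian")]]
Rcpp::IntegerVector cpp_hungarian(const arma::mat& cost) {
  const int n = cost.n_rows;
  std::vector<double> u(n + 1, 0), v(n + 1, 0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  const double INF = datum::inf;
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<bool> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = 0;
      double delta = INF;
      for (int j = 1; j <= n; ++j)
        if (!used[j]) {
          double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      for (int j = 0; j <= n; ++j)
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  Rcpp::IntegerVector match(n);  // match[i] = column assigned to row i (1-based)
  for (int j = 1; j <= n; ++j) match[p[j] - 1] = j;
  return match;
}
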