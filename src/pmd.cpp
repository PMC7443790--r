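// Penalized matrix decomposition core for sparse CCA.
//
// The alternating soft-thresholded power method operates on the cross-product
// matrix M = X'Y of two z-scored blocks.  Each update projects a gradient
// direction onto the intersection of the L2 unit ball and an L1 ball of
// budget c via soft-thresholding, with the threshold found by bisection.
// The permutation test re-runs the full sparsity grid search per permuted
// dataset, so these loops are compiled.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec soft(const vec& x, double lambda) {
  return sign(x) % clamp(abs(x) - lambda, 0.0, datum::inf);
}

// Project a (nonzero) direction onto {u : ||u||_2 = 1, ||u||_1 <= c}.
// Smallest feasible threshold by bisection; if the budget is below what any
// spread over the tied maxima can achieve, fall back to a one-hot vector at
// the first (index-order) maximum.
static vec l1_unit_project_impl(const vec& a, double c, double tol = 1e-10) {
  vec u = a / norm(a, 2);
  if (accu(abs(u)) <= c + 1e-12) return u;
  double hi = abs(a).max();
  uvec ties = find(abs(a) >= hi * (1.0 - 1e-12));
  if (std::sqrt((double)ties.n_elem) > c + 1e-10) {
    vec out(a.n_elem, fill::zeros);
    out(ties(0)) = (a(ties(0)) >= 0) ? 1.0 : -1.0;
    return out;
  }
  double lo = 0.0;
  for (int it = 0; it < 200 && (hi - lo) > tol; ++it) {
    double mid = 0.5 * (lo + hi);
    vec s = soft(a, mid);
    double n2 = norm(s, 2);
    if (n2 == 0.0) { hi = mid; continue; }
    if (accu(abs(s)) / n2 > c) lo = mid; else hi = mid;
  }
  vec s = soft(a, hi);
  return s / norm(s, 2);
}

// [[Rcpp::export(name = ".cpp_soft_threshold")]]
arma::vec cpp_soft_threshold(const arma::vec& x, double lambda) {
  return soft(x, lambda);
}

// [[Rcpp::export(name = ".cpp_l1_unit_project")]]
arma::vec cpp_l1_unit_project(const arma::vec& a, double c) {
  return l1_unit_project_impl(a, c);
}

static double pearson(const vec& x, const vec& y) {
  vec xc = x - mean(x), yc = y - mean(y);
  double denom = norm(xc, 2) * norm(yc, 2);
  if (denom == 0.0) return 0.0;
  return dot(xc, yc) / denom;
}

struct Rank1Fit {
  vec u, v;
  double r;
  int iters;
  bool converged;
};

// Alternating updates on a (possibly deflated) cross-product matrix M,
// initialized at its leading singular pair.  X and Y are needed only for
// the score correlation r.
static Rank1Fit pmd_rank1_impl(const mat& X, const mat& Y, const mat& M,
                               double c1, double c2,
                               int max_iter = 500, double tol = 1e-8,
                               const vec* u0 = nullptr, const vec* v0 = nullptr) {
  vec u, v;
  if (u0 && v0) {
    u = *u0; v = *v0;
  } else {
    mat U, V; vec s;
    svd_econ(U, s, V, M);
    u = U.col(0); v = V.col(0);
  }
  // make the starting pair feasible
  u = l1_unit_project_impl(u, c1);
  v = l1_unit_project_impl(v, c2);
  int it = 0;
  bool conv = false;
  for (; it < max_iter; ++it) {
    vec u_old = u, v_old = v;
    vec mu = M * v;
    if (norm(mu, 2) == 0.0) break;
    u = l1_unit_project_impl(mu, c1);
    vec mv = M.t() * u;
    if (norm(mv, 2) == 0.0) break;
    v = l1_unit_project_impl(mv, c2);
    double ch = std::max(abs(u - u_old).max(), abs(v - v_old).max());
    if (ch < tol) { conv = true; ++it; break; }
  }
  // sign convention: largest-|weight| entry of u positive (flip both sides)
  uword imax = index_max(abs(u));
  if (u(imax) < 0) { u = -u; v = -v; }
  Rank1Fit fit;
  fit.u = u; fit.v = v;
  fit.r = pearson(X * u, Y * v);
  fit.iters = it;
  fit.converged = conv;
  return fit;
}

// [[Rcpp::export(name = ".cpp_pmd_rank1")]]
Rcpp::List cpp_pmd_rank1(const arma::mat& X, const arma::mat& Y,
                         const arma::mat& M, double c1, double c2,
                         int max_iter, double tol) {
  Rank1Fit f = pmd_rank1_impl(X, Y, M, c1, c2, max_iter, tol);
  return Rcpp::List::create(
    Rcpp::Named("u") = f.u, Rcpp::Named("v") = f.v,
    Rcpp::Named("r") = f.r, Rcpp::Named("iterations") = f.iters,
    Rcpp::Named("converged") = f.converged);
}

struct GridFit {
  Rank1Fit best;
  double c1, c2;
  int i1, i2;          // 0-based grid indices of the optimum
  mat trace;           // r at every (c1, c2)
};

// Full grid search; ties in r (within 1e-10) broken toward smaller c1 + c2,
// then lexicographically by grid index.  The leading singular pair of M is
// computed once and reused as the starting point at every grid point.
static GridFit grid_search_impl(const mat& X, const mat& Y,
                                const vec& c1grid, const vec& c2grid,
                                int max_iter, double tol, bool keep_trace) {
  mat M = X.t() * Y;
  mat U, V; vec s;
  svd_econ(U, s, V, M);
  vec u0 = U.col(0), v0 = V.col(0);
  GridFit g;
  g.i1 = -1; g.i2 = -1; g.c1 = 0; g.c2 = 0;
  g.best.r = -datum::inf;
  if (keep_trace) g.trace.set_size(c1grid.n_elem, c2grid.n_elem);
  const double tie = 1e-10;
  double best_sum = datum::inf;
  for (uword i = 0; i < c1grid.n_elem; ++i) {
    for (uword j = 0; j < c2grid.n_elem; ++j) {
      Rank1Fit f = pmd_rank1_impl(X, Y, M, c1grid(i), c2grid(j),
                                  max_iter, tol, &u0, &v0);
      if (keep_trace) g.trace(i, j) = f.r;
      double sum = c1grid(i) + c2grid(j);
      bool better = f.r > g.best.r + tie ||
        (std::abs(f.r - g.best.r) <= tie && sum < best_sum - 1e-12);
      if (better) {
        g.best = f; g.c1 = c1grid(i); g.c2 = c2grid(j);
        g.i1 = (int)i; g.i2 = (int)j; best_sum = sum;
      }
    }
  }
  return g;
}

// [[Rcpp::export(name = ".cpp_grid_search")]]
Rcpp::List cpp_grid_search(const arma::mat& X, const arma::mat& Y,
                           const arma::vec& c1grid, const arma::vec& c2grid,
                           int max_iter, double tol) {
  GridFit g = grid_search_impl(X, Y, c1grid, c2grid, max_iter, tol, true);
  return Rcpp::List::create(
    Rcpp::Named("u") = g.best.u, Rcpp::Named("v") = g.best.v,
    Rcpp::Named("r") = g.best.r, Rcpp::Named("c1") = g.c1,
    Rcpp::Named("c2") = g.c2, Rcpp::Named("i1") = g.i1 + 1,
    Rcpp::Named("i2") = g.i2 + 1,
    Rcpp::Named("iterations") = g.best.iters,
    Rcpp::Named("converged") = g.best.converged,
    Rcpp::Named("trace") = g.trace);
}

// Per-permutation maxima of the grid-searched canonical correlation.
// perms: n x B matrix of 0-based row permutations applied to Y.
// [[Rcpp::export(name = ".cpp_perm_max_r")]]
arma::vec cpp_perm_max_r(const arma::mat& X, const arma::mat& Y,
                         const arma::vec& c1grid, const arma::vec& c2grid,
                         const arma::umat& perms, int max_iter, double tol) {
  vec out(perms.n_cols);
  for (uword b = 0; b < perms.n_cols; ++b) {
    mat Yp = Y.rows(perms.col(b));
    GridFit g = grid_search_impl(X, Yp, c1grid, c2grid, max_iter, tol, false);
    out(b) = g.best.r;
    if (b % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Fixed-sparsity permutation r (exploration mode; never used for reported p).
// [[Rcpp::export(name = ".cpp_perm_fixed_r")]]
arma::vec cpp_perm_fixed_r(const arma::mat& X, const arma::mat& Y,
                           double c1, double c2,
                           const arma::umat& perms, int max_iter, double tol) {
  vec out(perms.n_cols);
  for (uword b = 0; b < perms.n_cols; ++b) {
    mat Yp = Y.rows(perms.col(b));
    mat M = X.t() * Yp;
    Rank1Fit f = pmd_rank1_impl(X, Yp, M, c1, c2, max_iter, tol);
    out(b) = f.r;
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
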