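// Profiled Gaussian likelihood core for multi-regime OU / BM models on a
// time tree.  All functions work with the fixed-root (non-stationary) OU
// covariance V_ij = sigma2/(2a) * exp(-a(Ti+Tj-2ta)) * (1 - exp(-2a*ta)),
// where ta is the height of the pair's MRCA above the root.  At a given
// alpha both the optima (by GLS) and sigma2 (= Q/n) are profiled out, so
// fitting reduces to a 1-D search over log(alpha).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// OU covariance at sigma2 = 1 (the "shape" matrix W(alpha)); exploits
// symmetry so the transcendental work is done on one triangle only.
static arma::mat ou_shape(double alpha, const arma::mat& ta,
                          const arma::vec& depths) {
  int n = depths.n_elem;
  arma::mat W(n, n);
  double half = 0.5 / alpha;
  for (int j = 0; j < n; ++j) {
    for (int i = j; i < n; ++i) {
      double s = depths[i] + depths[j] - 2.0 * ta(i, j);
      double v = -half * std::exp(-alpha * s) *
                 std::expm1(-2.0 * alpha * ta(i, j));
      W(i, j) = v;
      W(j, i) = v;
    }
  }
  return W;
}

// Regression design for the optima: D[i, k] is the weight of optimum k in
// E[x_i].  Segment rows are (tip, optimum, t_start, t_end) with heights
// measured forward from the root; root_opt >= 0 folds the root state into
// that optimum's column, root_opt == -1 appends a free-X0 column.
static arma::mat ou_design(double alpha, const arma::vec& depths,
                           const arma::ivec& seg_tip, const arma::ivec& seg_opt,
                           const arma::vec& seg_start, const arma::vec& seg_end,
                           int k, int root_opt) {
  int n = depths.n_elem;
  int m = (root_opt >= 0) ? k : k + 1;
  arma::mat D(n, m, arma::fill::zeros);
  for (arma::uword r = 0; r < seg_tip.n_elem; ++r) {
    int i = seg_tip[r];
    double Ti = depths[i];
    D(i, seg_opt[r]) +=
        std::exp(-alpha * (Ti - seg_end[r])) -
        std::exp(-alpha * (Ti - seg_start[r]));
  }
  arma::vec w0 = arma::exp(-alpha * depths);
  if (root_opt >= 0)
    D.col(root_opt) += w0;
  else
    D.col(k) = w0;
  return D;
}

// Profile log-likelihood given a Cholesky factor of the shape matrix.
// Returns lnL, sigma2hat and the GLS coefficients.
static List gls_profile(const arma::mat& L, double logdetW,
                        const arma::mat& D, const arma::vec& x) {
  int n = x.n_elem;
  arma::mat Dz = arma::solve(arma::trimatl(L), D);
  arma::vec z = arma::solve(arma::trimatl(L), x);
  arma::mat A = Dz.t() * Dz;
  arma::vec b = Dz.t() * z;
  arma::vec beta;
  if (!arma::solve(beta, A, b, arma::solve_opts::no_approx)) {
    // rank-deficient design (e.g. free root state on an ultrametric tree,
    // where X0 is confounded with a constant shift of the optima): take the
    // minimum-norm solution; the fitted means, and hence lnL, are unique
    arma::mat Ainv;
    if (!arma::pinv(Ainv, A)) return List::create(_["lnL"] = R_NegInf);
    beta = Ainv * b;
  }
  arma::vec r = z - Dz * beta;
  double Q = arma::dot(r, r);
  double sigma2 = Q / n;
  if (!(sigma2 > 0.0) || !std::isfinite(sigma2))
    return List::create(_["lnL"] = R_NegInf);
  double lnL = -0.5 * n * (LOG2PI + 1.0) - 0.5 * n * std::log(sigma2) -
               0.5 * logdetW;
  return List::create(_["lnL"] = lnL, _["sigma2"] = sigma2,
                      _["coef"] = beta);
}

// [[Rcpp::export]]
List ou_profile_cpp(double alpha, const arma::mat& ta, const arma::vec& depths,
                    const arma::ivec& seg_tip, const arma::ivec& seg_opt,
                    const arma::vec& seg_start, const arma::vec& seg_end,
                    int k, int root_opt, const arma::vec& x) {
  arma::mat W = ou_shape(alpha, ta, depths);
  arma::mat L;
  if (!arma::chol(L, W, "lower"))
    return List::create(_["lnL"] = R_NegInf);
  double logdetW = 2.0 * arma::sum(arma::log(L.diag()));
  arma::mat D = ou_design(alpha, depths, seg_tip, seg_opt, seg_start, seg_end,
                          k, root_opt);
  return gls_profile(L, logdetW, D, x);
}

// Grid evaluation shared across datasets: one Cholesky per alpha, reused for
// every column of X.  Returns the n_alpha x n_dataset matrix of profile lnL.
// [[Rcpp::export]]
arma::mat ou_profile_grid_cpp(const arma::vec& alphas, const arma::mat& ta,
                              const arma::vec& depths, const arma::ivec& seg_tip,
                              const arma::ivec& seg_opt, const arma::vec& seg_start,
                              const arma::vec& seg_end, int k, int root_opt,
                              const arma::mat& X) {
  int n = depths.n_elem;
  int m = X.n_cols;
  arma::mat out(alphas.n_elem, m);
  out.fill(R_NegInf);
  for (arma::uword a = 0; a < alphas.n_elem; ++a) {
    double alpha = alphas[a];
    arma::mat W = ou_shape(alpha, ta, depths);
    arma::mat L;
    if (!arma::chol(L, W, "lower")) continue;
    double logdetW = 2.0 * arma::sum(arma::log(L.diag()));
    arma::mat D = ou_design(alpha, depths, seg_tip, seg_opt, seg_start,
                            seg_end, k, root_opt);
    arma::mat Dz = arma::solve(arma::trimatl(L), D);
    arma::mat Z = arma::solve(arma::trimatl(L), X);
    arma::mat A = Dz.t() * Dz;
    arma::mat B = Dz.t() * Z;               // m_coef x m
    arma::mat Beta;
    if (!arma::solve(Beta, A, B, arma::solve_opts::no_approx)) {
      arma::mat Ainv;
      if (!arma::pinv(Ainv, A)) continue;
      Beta = Ainv * B;
    }
    arma::mat R = Z - Dz * Beta;
    arma::rowvec Q = arma::sum(arma::square(R), 0);
    for (int j = 0; j < m; ++j) {
      double sigma2 = Q[j] / n;
      if (sigma2 > 0.0 && std::isfinite(sigma2))
        out(a, j) = -0.5 * n * (LOG2PI + 1.0) - 0.5 * n * std::log(sigma2) -
                    0.5 * logdetW;
    }
  }
  return out;
}

// lnL-only evaluation used by the 1-D search.
static double profile_lnl(double alpha, const arma::mat& ta,
                          const arma::vec& depths, const arma::ivec& seg_tip,
                          const arma::ivec& seg_opt, const arma::vec& seg_start,
                          const arma::vec& seg_end, int k, int root_opt,
                          const arma::vec& x) {
  arma::mat W = ou_shape(alpha, ta, depths);
  arma::mat L;
  if (!arma::chol(L, W, "lower")) return -arma::datum::inf;
  double logdetW = 2.0 * arma::sum(arma::log(L.diag()));
  arma::mat D = ou_design(alpha, depths, seg_tip, seg_opt, seg_start, seg_end,
                          k, root_opt);
  int n = x.n_elem;
  arma::mat Dz = arma::solve(arma::trimatl(L), D);
  arma::vec z = arma::solve(arma::trimatl(L), x);
  arma::mat A = Dz.t() * Dz;
  arma::vec b = Dz.t() * z;
  arma::vec beta;
  if (!arma::solve(beta, A, b, arma::solve_opts::no_approx)) {
    arma::mat Ainv;
    if (!arma::pinv(Ainv, A)) return -arma::datum::inf;
    beta = Ainv * b;
  }
  arma::vec r = z - Dz * beta;
  double sigma2 = arma::dot(r, r) / n;
  if (!(sigma2 > 0.0) || !std::isfinite(sigma2)) return -arma::datum::inf;
  return -0.5 * n * (LOG2PI + 1.0) - 0.5 * n * std::log(sigma2) -
         0.5 * logdetW;
}

// Brent's method maximizing f(la) = profile lnL at alpha = exp(la) on
// [la_lo, la_hi]; tol is the absolute tolerance on la.
template <typename F>
static double brent_max(F f, double lo, double hi, double tol,
                        double* fbest) {
  const double gold = 0.3819660112501051;
  double a = lo, b = hi;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 100; ++iter) {
    double m = 0.5 * (a + b);
    double tol1 = tol * (std::abs(x) + 1e-10) + 1e-12;
    double tol2 = 2.0 * tol1;
    if (std::abs(x - m) <= tol2 - 0.5 * (b - a)) break;
    double p = 0.0, q = 0.0, r = 0.0;
    bool parab = false;
    if (std::abs(e) > tol1) {
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::abs(q);
      double etemp = e;
      e = d;
      if (std::abs(p) < std::abs(0.5 * q * etemp) && p > q * (a - x) &&
          p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (m > x) ? tol1 : -tol1;
        parab = true;
      }
    }
    if (!parab) {
      e = (x < m) ? b - x : a - x;
      d = gold * e;
    }
    double u = (std::abs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu >= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu >= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu >= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  *fbest = fx;
  return x;
}

// Full batch OU fit: grid stage with one Cholesky per alpha shared across
// datasets, then per-dataset Brent refinement between the neighbouring grid
// points (extended to the search bounds at the grid ends).
// [[Rcpp::export]]
List ou_fit_batch_cpp(const arma::mat& X, const arma::mat& ta,
                      const arma::vec& depths, const arma::ivec& seg_tip,
                      const arma::ivec& seg_opt, const arma::vec& seg_start,
                      const arma::vec& seg_end, int k, int root_opt,
                      const arma::vec& alpha_grid, double alpha_lo,
                      double alpha_hi, double tol) {
  int m = X.n_cols;
  int ng = alpha_grid.n_elem;
  arma::mat grid_lnl = ou_profile_grid_cpp(alpha_grid, ta, depths, seg_tip,
                                           seg_opt, seg_start, seg_end, k,
                                           root_opt, X);
  arma::vec la(ng);
  for (int a = 0; a < ng; ++a) la[a] = std::log(alpha_grid[a]);
  int nco = (root_opt >= 0) ? k : k + 1;
  arma::vec alpha_out(m), sigma2_out(m), lnl_out(m);
  arma::mat coef_out(m, nco);
  arma::ivec boundary(m, arma::fill::zeros);
  for (int j = 0; j < m; ++j) {
    arma::vec xj = X.col(j);
    int b = grid_lnl.col(j).index_max();
    double lo = (b == 0) ? std::log(alpha_lo) : la[b - 1];
    double hi = (b == ng - 1) ? std::log(alpha_hi) : la[b + 1];
    auto f = [&](double lav) {
      return profile_lnl(std::exp(lav), ta, depths, seg_tip, seg_opt,
                         seg_start, seg_end, k, root_opt, xj);
    };
    double fbest;
    double labest = brent_max(f, lo, hi, tol, &fbest);
    double ahat = std::exp(labest);
    if (std::isfinite(grid_lnl(b, j)) && grid_lnl(b, j) > fbest)
      ahat = alpha_grid[b];
    List fin = ou_profile_cpp(ahat, ta, depths, seg_tip, seg_opt, seg_start,
                              seg_end, k, root_opt, xj);
    double lnl = as<double>(fin["lnL"]);
    alpha_out[j] = ahat;
    lnl_out[j] = lnl;
    if (std::isfinite(lnl)) {
      sigma2_out[j] = as<double>(fin["sigma2"]);
      arma::vec cf = as<arma::vec>(fin["coef"]);
      coef_out.row(j) = cf.t();
    } else {
      sigma2_out[j] = NA_REAL;
      coef_out.row(j).fill(NA_REAL);
    }
    boundary[j] = (ahat / alpha_hi > 0.999) || (alpha_lo / ahat > 0.999);
  }
  return List::create(_["alpha"] = alpha_out, _["sigma2"] = sigma2_out,
                      _["lnL"] = lnl_out, _["coef"] = coef_out,
                      _["boundary"] = boundary);
}

// BM profile likelihood with a precomputed Cholesky factor of the BM shape
// matrix (ta with diagonal equal to tip depths); the only coefficient is the
// root state X0.
// [[Rcpp::export]]
List bm_profile_chol_cpp(const arma::mat& L, double logdetW,
                         const arma::vec& x) {
  arma::mat D(x.n_elem, 1, arma::fill::ones);
  return gls_profile(L, logdetW, D, x);
}
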