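#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Direct-form II transposed IIR filter, zero initial conditions.
static void iir_filter(const arma::vec& b, const arma::vec& a, arma::vec& x) {
  const arma::uword nb = b.n_elem, na = a.n_elem, n = x.n_elem;
  arma::vec z(std::max(nb, na) - 1, arma::fill::zeros);
  const arma::uword nz = z.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (nz ? z[0] : 0.0);
    for (arma::uword j = 1; j < nz; ++j) {
      z[j - 1] = (j < nb ? b[j] * xi : 0.0) + z[j] - (j < na ? a[j] * yi : 0.0);
    }
    if (nz) z[nz - 1] = (nz < nb ? b[nz] * xi : 0.0) - (nz < na ? a[nz] * yi : 0.0);
    x[i] = yi;
  }
}

// Forward-backward (zero-phase) filtering of each column of X.
// Matches signal::filtfilt: append 2*max(na,nb) zeros, filter, reverse,
// filter again, reverse, truncate to the original length.
// [[Rcpp::export(name = ".filtfilt_mat")]]
arma::mat filtfilt_mat(const arma::vec& b, const arma::vec& a, const arma::mat& X) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const arma::uword pad = 2 * std::max(a.n_elem, b.n_elem);
  arma::mat out(n, p);
  arma::vec work(n + pad);
  for (arma::uword j = 0; j < p; ++j) {
    work.zeros();
    work.head(n) = X.col(j);
    iir_filter(b, a, work);
    work = arma::reverse(work);
    iir_filter(b, a, work);
    work = arma::reverse(work);
    out.col(j) = work.head(n);
  }
  return out;
}

// OLS coefficient vector via normal equations with a pinv fallback.
static arma::vec ols(const arma::mat& X, const arma::vec& y) {
  arma::vec beta;
  if (!arma::solve(beta, X.t() * X, X.t() * y, arma::solve_opts::no_approx)) {
    beta = arma::pinv(X.t() * X) * (X.t() * y);
  }
  return beta;
}

// Mediation paths (a, b, c, cprime, ab) for data columns [iv, m, dv, covs...].
// Covariates enter every regression; an intercept is always included.
static arma::rowvec paths_one(const arma::mat& D) {
  const arma::uword n = D.n_rows, ncov = D.n_cols - 3;
  arma::vec iv = D.col(0), m = D.col(1), dv = D.col(2);
  arma::mat covs = ncov ? D.cols(3, D.n_cols - 1) : arma::mat(n, 0);
  arma::vec ones(n, arma::fill::ones);

  arma::mat X1 = arma::join_rows(ones, iv, covs);          // M ~ IV
  arma::mat X3 = arma::join_rows(ones, m, iv);             // DV ~ M + IV
  if (ncov) X3 = arma::join_rows(X3, covs);

  double a  = ols(X1, m)(1);
  double c  = ols(X1, dv)(1);
  arma::vec b3 = ols(X3, dv);
  double b = b3(1), cp = b3(2);
  arma::rowvec out(5);
  out(0) = a; out(1) = b; out(2) = c; out(3) = cp; out(4) = a * b;
  return out;
}

// [[Rcpp::export(name = ".fit_paths_mat")]]
arma::rowvec fit_paths_mat(const arma::mat& D) { return paths_one(D); }

// Bootstrap of mediation paths: resample rows with replacement B times,
// refit the three regressions per draw. Uses R's RNG (honours set.seed()).
// Draws with a constant iv, m or dv are discarded and counted.
// [[Rcpp::export(name = ".boot_paths")]]
List boot_paths(const arma::mat& D, const int B) {
  const arma::uword n = D.n_rows;
  arma::mat est(B, 5);
  int kept = 0, discarded = 0;
  arma::mat Db(n, D.n_cols);
  RNGScope scope;
  for (int bI = 0; bI < B; ++bI) {
    for (arma::uword i = 0; i < n; ++i) {
      arma::uword idx = (arma::uword)(unif_rand() * n);
      if (idx >= n) idx = n - 1;
      Db.row(i) = D.row(idx);
    }
    bool degenerate = false;
    for (arma::uword j = 0; j < 3; ++j) {
      if (arma::stddev(Db.col(j)) < 1e-12) { degenerate = true; break; }
    }
    if (degenerate) { ++discarded; continue; }
    est.row(kept++) = paths_one(Db);
  }
  return List::create(_["estimates"] = est.rows(0, kept - 1),
                      _["discarded"] = discarded);
}

// Per-voxel OLS t-statistics for one regressor across many columns of Y.
// X: n x k design, Y: n x p responses, coef_index: 1-based column of X.
// Returns 3 x p matrix: slope, t, sigma2.
// [[Rcpp::export(name = ".massuni_t")]]
arma::mat massuni_t(const arma::mat& X, const arma::mat& Y, const int coef_index) {
  const arma::uword n = X.n_rows, k = X.n_cols, p = Y.n_cols;
  arma::mat XtX = X.t() * X;
  arma::mat XtXi = arma::pinv(XtX);
  arma::mat H = XtXi * X.t();                 // k x n
  arma::mat beta = H * Y;                     // k x p
  arma::mat res = Y - X * beta;               // n x p
  arma::rowvec rss = arma::sum(arma::square(res), 0);
  double df = (double)(n - k);
  arma::rowvec sigma2 = rss / df;
  double v = XtXi(coef_index - 1, coef_index - 1);
  arma::mat out(3, p);
  out.row(0) = beta.row(coef_index - 1);
  out.row(1) = beta.row(coef_index - 1) / arma::sqrt(sigma2 * v);
  out.row(2) = sigma2;
  return out;
}
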