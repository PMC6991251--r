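// Weighted logistic Newton solver for designs with one intercept per time
// stratum plus a small dense covariate block. The bootstrap re-runs this
// fit thousands of times per analysis with only the case weights changing,
// so the inner loop lives in C++; the pure-R implementation of the same
// algorithm is kept as the reference and the two are asserted equal in the
// test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".blocked_logit_fit_cpp")]]
List blocked_logit_fit_cpp(const IntegerVector& qidx, int K,
                           const arma::mat& Z, const arma::vec& y,
                           const arma::vec& w, const arma::vec& a0,
                           const arma::vec& bz0, double tol, int maxit,
                           bool want_logp) {
  const int n = y.n_elem;
  const int p = Z.n_cols;
  arma::vec a = a0, bz = bz0;
  arma::vec eta(n), mu(n), r(n), wt(n);
  arma::vec sa(K), A(K), da(K);
  arma::mat B(K, p);
  bool converged = false;
  int it = 0;

  while (it < maxit) {
    ++it;
    if (p > 0) eta = Z * bz; else eta.zeros();
    for (int i = 0; i < n; ++i) {
      eta[i] += a[qidx[i] - 1];
      double m = 1.0 / (1.0 + std::exp(-eta[i]));
      mu[i] = m;
      r[i] = w[i] * (y[i] - m);
      double v = w[i] * m * (1.0 - m);
      wt[i] = (v < 1e-12) ? 1e-12 : v;
    }
    sa.zeros();
    A.fill(1e-10);
    B.zeros();
    for (int i = 0; i < n; ++i) {
      int k = qidx[i] - 1;
      sa[k] += r[i];
      A[k] += wt[i];
      for (int j = 0; j < p; ++j) B(k, j) += wt[i] * Z(i, j);
    }
    double maxstep = 0.0;
    arma::vec dz;
    if (p > 0) {
      arma::vec sz = Z.t() * r;
      arma::mat Cm = Z.t() * (Z.each_col() % wt);
      arma::mat S = Cm - B.t() * (B.each_col() / A);
      arma::vec rhs = sz - B.t() * (sa / A);
      bool ok = arma::solve(dz, S, rhs, arma::solve_opts::no_approx);
      if (!ok) stop("singular information matrix in blocked logistic fit");
      da = (sa - B * dz) / A;
      bz += dz;
      for (int j = 0; j < p; ++j)
        maxstep = std::max(maxstep, std::fabs(dz[j]));
    } else {
      da = sa / A;
    }
    for (int k = 0; k < K; ++k) {
      double anew = a[k] + da[k];
      // strata with no response variation drift to +/-Inf under a
      // resample; clamp and exempt from the convergence check
      bool runaway = std::fabs(anew) > 12.0 && da[k] * anew > 0.0;
      if (anew > 18.0) anew = 18.0;
      if (anew < -18.0) anew = -18.0;
      if (!runaway) maxstep = std::max(maxstep, std::fabs(anew - a[k]));
      a[k] = anew;
    }
    if (maxstep < tol) { converged = true; break; }
  }

  List out = List::create(_["a"] = a, _["bz"] = bz,
                          _["iterations"] = it,
                          _["converged"] = converged);
  if (want_logp) {
    // log P(y = 1) for every row: -log(1 + exp(-eta))
    arma::vec logp(n);
    if (p > 0) eta = Z * bz; else eta.zeros();
    for (int i = 0; i < n; ++i) {
      eta[i] += a[qidx[i] - 1];
      double e = eta[i];
      logp[i] = (e > 0) ? -std::log1p(std::exp(-e))
                        : e - std::log1p(std::exp(e));
    }
    out["logp"] = logp;
  }
  if (p > 0) {
    // Schur complement inverse = covariance of bz at the optimum
    arma::mat Cm = Z.t() * (Z.each_col() % wt);
    arma::mat S = Cm - B.t() * (B.each_col() / A);
    out["vcov_bz"] = arma::inv(S);
  }
  return out;
}
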