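// Dual coordinate descent for L1-loss (epsilon-insensitive) support vector
// regression. Solves
//   min_beta  1/2 beta' Q beta - y' beta + eps * ||beta||_1,
//   beta_i in [-C, C],
// where Q = X X' for the linear kernel (the bias is absorbed by an
// augmented constant feature appended in R) or Q = K for a precomputed
// kernel. The primal weight vector is w = X' beta. Updates follow the
// standard soft-threshold closed form per coordinate; sweeps are cyclic so
// the solver is deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double cd_update(double beta_i, double G, double Qii,
                               double C, double eps) {
  double bp = beta_i - (G + eps) / Qii;
  double bn = beta_i - (G - eps) / Qii;
  double nb;
  if (bp > 0.0)      nb = std::min(bp, C);
  else if (bn < 0.0) nb = std::max(bn, -C);
  else               nb = 0.0;
  return nb;
}

// Xt is features x observations (column i = observation i), so each
// coordinate update touches a contiguous column.
// [[Rcpp::export(name = ".svr_cd_linear")]]
Rcpp::List svr_cd_linear(const arma::mat& Xt, const arma::vec& y,
                         double C, double eps,
                         double tol = 1e-4, int max_sweeps = 200) {
  const uword n = Xt.n_cols;
  vec beta(n, fill::zeros);
  vec w(Xt.n_rows, fill::zeros);
  vec Qii(n);
  for (uword i = 0; i < n; ++i) Qii(i) = dot(Xt.col(i), Xt.col(i));
  int sweep = 0;
  for (; sweep < max_sweeps; ++sweep) {
    double max_delta = 0.0;
    for (uword i = 0; i < n; ++i) {
      if (Qii(i) <= 0) continue;
      double G = dot(Xt.col(i), w) - y(i);
      double nb = cd_update(beta(i), G, Qii(i), C, eps);
      double d = nb - beta(i);
      if (d != 0.0) {
        w += d * Xt.col(i);
        beta(i) = nb;
        max_delta = std::max(max_delta, std::fabs(d));
      }
    }
    if (max_delta < tol * C) break;
  }
  return Rcpp::List::create(Rcpp::Named("w") = w,
                            Rcpp::Named("beta") = beta,
                            Rcpp::Named("sweeps") = sweep + 1);
}

// [[Rcpp::export(name = ".svr_cd_kernel")]]
Rcpp::List svr_cd_kernel(const arma::mat& Q, const arma::vec& y,
                         double C, double eps,
                         double tol = 1e-4, int max_sweeps = 200) {
  const uword n = Q.n_rows;
  vec beta(n, fill::zeros);
  vec qb(n, fill::zeros); // Q beta
  int sweep = 0;
  for (; sweep < max_sweeps; ++sweep) {
    double max_delta = 0.0;
    for (uword i = 0; i < n; ++i) {
      double Qii = Q(i, i);
      if (Qii <= 0) continue;
      double G = qb(i) - y(i);
      double nb = cd_update(beta(i), G, Qii, C, eps);
      double d = nb - beta(i);
      if (d != 0.0) {
        qb += d * Q.col(i);
        beta(i) = nb;
        max_delta = std::max(max_delta, std::fabs(d));
      }
    }
    if (max_delta < tol * C) break;
  }
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("sweeps") = sweep + 1);
}
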