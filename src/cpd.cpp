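// Coherent point drift E-step.  X: N x 3 target, Y: M x 3 (transformed)
// source, isotropic variance sigma2, uniform outlier weight w.
// Returns P1 (M), Pt1 (N), PX (M x 3) and the negative log-likelihood.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_cpd_estep(const arma::mat& X, const arma::mat& Y, double sigma2, double w) {
  const int N = X.n_rows, M = Y.n_rows;
  const double c = std::pow(2.0 * M_PI * sigma2, 1.5) * (w / (1.0 - w)) *
                   ((double)M / (double)N);
  arma::vec P1(M, arma::fill::zeros);
  arma::vec Pt1(N, arma::fill::zeros);
  arma::mat PX(M, 3, arma::fill::zeros);
  double L = 0.0;
  const double inv2s = 1.0 / (2.0 * sigma2);
  arma::vec num(M);
  for (int n = 0; n < N; ++n) {
    double xn0 = X(n, 0), xn1 = X(n, 1), xn2 = X(n, 2);
    for (int m = 0; m < M; ++m) {
      double d0 = xn0 - Y(m, 0), d1 = xn1 - Y(m, 1), d2 = xn2 - Y(m, 2);
      num[m] = std::exp(-(d0 * d0 + d1 * d1 + d2 * d2) * inv2s);
    }
    double den = arma::accu(num) + c;
    if (den < 1e-300) den = 1e-300;
    L -= std::log(den);
    Pt1[n] = 1.0 - c / den;
    double inv_den = 1.0 / den;
    for (int m = 0; m < M; ++m) {
      double p = num[m] * inv_den;
      if (p > 0.0) {
        P1[m] += p;
        PX(m, 0) += p * xn0;
        PX(m, 1) += p * xn1;
        PX(m, 2) += p * xn2;
      }
    }
  }
  L += N * 1.5 * std::log(sigma2);
  return List::create(_["P1"] = P1, _["Pt1"] = Pt1, _["PX"] = PX, _["L"] = L);
}
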