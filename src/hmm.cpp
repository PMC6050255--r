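#include <Rcpp.h>
using namespace Rcpp;

// Log-space forward-backward for a two-state HMM over a single chain.
// logem: n x 2 matrix of log emission densities (col 0 = null state),
// logpi: length-2 log initial distribution, logA: 2 x 2 log transition
// matrix (rows = from). Returns per-position posteriors (gamma), summed
// expected transition counts (xi) and the chain log-likelihood.
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logem, NumericVector logpi,
                          NumericMatrix logA) {
  const int n = logem.nrow();
  const int K = 2;
  NumericMatrix la(n, K), lb(n, K), gamma(n, K);

  for (int k = 0; k < K; ++k) la(0, k) = logpi[k] + logem(0, k);
  for (int i = 1; i < n; ++i) {
    for (int k = 0; k < K; ++k) {
      double acc[2], m = R_NegInf;
      for (int j = 0; j < K; ++j) {
        acc[j] = la(i - 1, j) + logA(j, k);
        if (acc[j] > m) m = acc[j];
      }
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += std::exp(acc[j] - m);
      la(i, k) = m + std::log(s) + logem(i, k);
    }
  }
  double m0 = std::max(la(n - 1, 0), la(n - 1, 1));
  double ll = m0 + std::log(std::exp(la(n - 1, 0) - m0) +
                            std::exp(la(n - 1, 1) - m0));

  lb(n - 1, 0) = 0.0;
  lb(n - 1, 1) = 0.0;
  for (int i = n - 2; i >= 0; --i) {
    for (int k = 0; k < K; ++k) {
      double acc[2], m = R_NegInf;
      for (int j = 0; j < K; ++j) {
        acc[j] = logA(k, j) + logem(i + 1, j) + lb(i + 1, j);
        if (acc[j] > m) m = acc[j];
      }
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += std::exp(acc[j] - m);
      lb(i, k) = m + std::log(s);
    }
  }

  for (int i = 0; i < n; ++i) {
    double g0 = la(i, 0) + lb(i, 0), g1 = la(i, 1) + lb(i, 1);
    double m = std::max(g0, g1);
    double s = std::exp(g0 - m) + std::exp(g1 - m);
    gamma(i, 0) = std::exp(g0 - m) / s;
    gamma(i, 1) = std::exp(g1 - m) / s;
  }

  NumericMatrix xi(K, K);
  for (int i = 0; i + 1 < n; ++i) {
    double v[2][2], m = R_NegInf;
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k) {
        v[j][k] = la(i, j) + logA(j, k) + logem(i + 1, k) + lb(i + 1, k);
        if (v[j][k] > m) m = v[j][k];
      }
    }
    double s = 0.0;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) s += std::exp(v[j][k] - m);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) xi(j, k) += std::exp(v[j][k] - m) / s;
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = ll);
}
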