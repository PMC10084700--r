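#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward E-step for a K-state Gaussian HMM (Rabiner
// scaling). Returns the log-likelihood, posterior state probabilities
// gamma (T x K) and summed transition posteriors xi_sum (K x K).
// [[Rcpp::export]]
List fb_estep(NumericVector y, NumericVector mu, NumericVector sigma,
              NumericMatrix trans, NumericVector init) {
  const int T = y.size(), K = mu.size();
  NumericMatrix b(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double d = R::dnorm(y[t], mu[k], sigma[k], 0);
      b(t, k) = (d > 1e-300) ? d : 1e-300;
    }

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * b(0, k); s += alpha(0, k); }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * trans(i, j);
      a *= b(t, j);
      alpha(t, j) = a;
      s += a;
    }
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += trans(i, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, i) = a / c[t + 1];
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t + 1 < T; ++t)
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += alpha(t, i) * trans(i, j) * b(t + 1, j) * beta(t + 1, j) / c[t + 1];

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi_sum"] = xi);
}

// Viterbi decoding in log space. Ties are broken toward the lower state
// index, deterministically, by strict-improvement comparisons.
// [[Rcpp::export]]
IntegerVector viterbi_path(NumericVector y, NumericVector mu,
                           NumericVector sigma, NumericMatrix trans,
                           NumericVector init) {
  const int T = y.size(), K = mu.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  NumericMatrix lb(T, K), la(K, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      lb(t, k) = R::dnorm(y[t], mu[k], sigma[k], 1);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j)
      la(i, j) = std::log(trans(i, j));
  for (int k = 0; k < K; ++k)
    delta(0, k) = std::log(init[k]) + lb(0, k);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < K; ++j) {
      int arg = 0;
      double best = delta(t - 1, 0) + la(0, j);
      for (int i = 1; i < K; ++i) {
        double cand = delta(t - 1, i) + la(i, j);
        if (cand > best) { best = cand; arg = i; }
      }
      delta(t, j) = best + lb(t, j);
      psi(t, j) = arg;
    }
  IntegerVector path(T);
  int arg = 0;
  double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1;  // 1-based state indices
}
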