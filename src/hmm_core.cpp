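#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for an HMM with precomputed (possibly unnormalized)
// log start weights, log transition weights and per-frame log emission
// weights. Used by the variational E-step, where the weights are geometric
// means exp(E[log pi]), exp(E[log A]), exp(E[log p(y|z)]) and are therefore
// sub-stochastic; the returned log-normalizer is the variational ln Z-tilde.

static inline double logsumexp2(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  if (!R_FINITE(m)) return m;
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List fb_hmm(NumericVector log_pi, NumericMatrix log_A, NumericMatrix log_B) {
  const int T = log_B.nrow(), K = log_B.ncol();
  if (log_pi.size() != K || log_A.nrow() != K || log_A.ncol() != K)
    stop("dimension mismatch in fb_hmm");
  if (K * K > 64) stop("fb_hmm supports at most 8 states");

  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector c(T);           // per-frame log scaling constants
  std::vector<double> work(K);

  // forward
  for (int k = 0; k < K; ++k) work[k] = log_pi[k] + log_B(0, k);
  double c0 = logsumexp2(work);
  c[0] = c0;
  for (int k = 0; k < K; ++k) alpha(0, k) = std::exp(work[k] - c0);
  for (int t = 1; t < T; ++t) {
    double cmax = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha(t - 1, j) * std::exp(log_A(j, k));
      double v = std::log(s) + log_B(t, k);
      work[k] = v;
      if (v > cmax) cmax = v;
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(work[k] - cmax);
    double ct = cmax + std::log(s);
    c[t] = ct;
    for (int k = 0; k < K; ++k) alpha(t, k) = std::exp(work[k] - ct);
  }

  // backward (scaled by the same constants)
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k)
        s += std::exp(log_A(j, k) + log_B(t + 1, k)) * beta(t + 1, k);
      beta(t, j) = s * std::exp(-c[t + 1]);
    }
  }

  // marginals and summed two-slice counts
  NumericMatrix xi(K, K);
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }
  for (int t = 0; t < T - 1; ++t) {
    double s = 0.0;
    double tmp[64];
    int idx = 0;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) {
        double v = alpha(t, j) * std::exp(log_A(j, k) + log_B(t + 1, k) - c[t + 1]) * beta(t + 1, k);
        tmp[idx++] = v;
        s += v;
      }
    idx = 0;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) xi(j, k) += tmp[idx++] / s;
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += c[t];

  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = loglik);
}

// Viterbi decoding; ties broken toward the lowest state index.
// [[Rcpp::export]]
IntegerVector viterbi_hmm(NumericVector log_pi, NumericMatrix log_A, NumericMatrix log_B) {
  const int T = log_B.nrow(), K = log_B.ncol();
  if (log_pi.size() != K || log_A.nrow() != K || log_A.ncol() != K)
    stop("dimension mismatch in viterbi_hmm");

  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = log_pi[k] + log_B(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + log_A(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + log_A(j, k);
        if (v > best) { best = v; arg = j; }   // strict: earlier index wins ties
      }
      delta(t, k) = best + log_B(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = delta(T - 1, 0);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
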