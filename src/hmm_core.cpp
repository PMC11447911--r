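#include <Rcpp.h>
using namespace Rcpp;

// log-sum-exp of a K-vector stored in buf[0..K)
static double lse(const std::vector<double>& buf) {
  double m = R_NegInf;
  for (double v : buf) if (v > m) m = v;
  if (!R_FINITE(m)) return R_NegInf;
  double s = 0.0;
  for (double v : buf) s += std::exp(v - m);
  return m + std::log(s);
}

//' Forward-backward pass for one observation sequence.
//'
//' All inputs are on the log scale. Returns the smoothed state probabilities
//' (gamma, T x K, natural scale), the matrix of expected transition counts
//' summed over time (xi_sum, K x K, natural scale) and the sequence
//' log-likelihood.
//'
//' @param log_pi length-K log initial distribution
//' @param log_A K x K log transition matrix (rows: from)
//' @param log_B T x K log emission densities per time step and state
//' @noRd
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericVector log_pi, NumericMatrix log_A, NumericMatrix log_B) {
  const int T = log_B.nrow(), K = log_B.ncol();
  NumericMatrix la(T, K), lb(T, K);
  std::vector<double> buf(K);

  // forward
  for (int k = 0; k < K; ++k) la(0, k) = log_pi[k] + log_B(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) buf[j] = la(t - 1, j) + log_A(j, k);
      la(t, k) = lse(buf) + log_B(t, k);
    }
  }
  for (int k = 0; k < K; ++k) buf[k] = la(T - 1, k);
  const double loglik = lse(buf);

  // backward
  for (int k = 0; k < K; ++k) lb(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) buf[j] = log_A(k, j) + log_B(t + 1, j) + lb(t + 1, j);
      lb(t, k) = lse(buf);
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      gamma(t, k) = std::exp(la(t, k) + lb(t, k) - loglik);

  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t)
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += std::exp(la(t, j) + log_A(j, k) + log_B(t + 1, k) +
                             lb(t + 1, k) - loglik);

  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi,
                      _["loglik"] = loglik);
}

//' Viterbi decoding for one observation sequence (log-scale inputs).
//'
//' Ties are broken toward the lower state index (deterministic).
//' Returns the 1-based most probable state path.
//' @noRd
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericVector log_pi, NumericMatrix log_A,
                          NumericMatrix log_B) {
  const int T = log_B.nrow(), K = log_B.ncol();
  NumericMatrix d(T, K);
  IntegerMatrix psi(T, K);

  for (int k = 0; k < K; ++k) d(0, k) = log_pi[k] + log_B(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      int arg = 0;
      double best = d(t - 1, 0) + log_A(0, k);
      for (int j = 1; j < K; ++j) {
        double v = d(t - 1, j) + log_A(j, k);
        if (v > best) { best = v; arg = j; }
      }
      d(t, k) = best + log_B(t, k);
      psi(t, k) = arg;
    }
  }

  IntegerVector path(T);
  int arg = 0;
  double best = d(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (d(T - 1, k) > best) { best = d(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
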