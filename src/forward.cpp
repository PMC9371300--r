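#include <Rcpp.h>
using namespace Rcpp;

// Observed-candidate emission probabilities for all strata and states:
// X is ((J+1)*n) x q, candidate-major with the observed step first in
// each stratum; beta is K x q.  Softmax over the J+1 candidates of each
// stratum, evaluated with max-subtraction.  Returns n x K.
// [[Rcpp::export(name = ".emission_obs_cpp")]]
NumericMatrix emission_obs_cpp(NumericMatrix X, NumericMatrix beta,
                               int Jp1) {
  int q = X.ncol(), K = beta.nrow();
  int n = X.nrow() / Jp1;
  NumericMatrix out(n, K);
  std::vector<double> s(Jp1);
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int j = 0; j < Jp1; ++j) {
        double a = 0.0;
        int row = i * Jp1 + j;
        for (int c = 0; c < q; ++c) a += X(row, c) * beta(k, c);
        s[j] = a;
        if (a > mx) mx = a;
      }
      double denom = 0.0;
      for (int j = 0; j < Jp1; ++j) denom += std::exp(s[j] - mx);
      out(i, k) = std::exp(s[0] - mx) / denom;
    }
  }
  return out;
}

// Scaled forward recursion over segment groups.
// e: n x K emission probabilities of the observed candidates;
// group: integer group label per stratum (consecutive strata of a group
// are contiguous); delta: initial distribution used at each group start.
// Returns the total log-likelihood.
// [[Rcpp::export(name = ".forward_ll_cpp")]]
double forward_ll_cpp(NumericMatrix e, NumericMatrix Gamma,
                      NumericVector delta, IntegerVector group) {
  int n = e.nrow(), K = e.ncol();
  double ll = 0.0;
  std::vector<double> phi(K), v(K);
  int prev = NA_INTEGER;
  for (int t = 0; t < n; ++t) {
    bool first = (t == 0) || (group[t] != prev);
    prev = group[t];
    double ct = 0.0;
    for (int k = 0; k < K; ++k) {
      double p;
      if (first) {
        p = delta[k];
      } else {
        p = 0.0;
        for (int j = 0; j < K; ++j) p += phi[j] * Gamma(j, k);
      }
      v[k] = p * e(t, k);
      ct += v[k];
    }
    if (!(ct > 0) || !R_finite(ct)) return R_NegInf;
    ll += std::log(ct);
    for (int k = 0; k < K; ++k) phi[k] = v[k] / ct;
  }
  return ll;
}

// Predictive and filtered state probabilities from the same recursion.
// Returns an n x 2K matrix: [pred | filt].
// [[Rcpp::export(name = ".forward_probs_cpp")]]
NumericMatrix forward_probs_cpp(NumericMatrix e, NumericMatrix Gamma,
                                NumericVector delta, IntegerVector group) {
  int n = e.nrow(), K = e.ncol();
  NumericMatrix out(n, 2 * K);
  std::vector<double> phi(K), v(K);
  int prev = NA_INTEGER;
  for (int t = 0; t < n; ++t) {
    bool first = (t == 0) || (group[t] != prev);
    prev = group[t];
    double ct = 0.0;
    for (int k = 0; k < K; ++k) {
      double p;
      if (first) {
        p = delta[k];
      } else {
        p = 0.0;
        for (int j = 0; j < K; ++j) p += phi[j] * Gamma(j, k);
      }
      out(t, k) = p;
      v[k] = p * e(t, k);
      ct += v[k];
    }
    for (int k = 0; k < K; ++k) {
      phi[k] = v[k] / ct;
      out(t, K + k) = phi[k];
    }
  }
  return out;
}
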