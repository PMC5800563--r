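#include <Rcpp.h>
using namespace Rcpp;

// Per-baseline-interval integrated dose-response load for the log-linear
// (Cox-form) hazard: A[k] = sum over segments in interval k of
// dur * exp(X beta).  This is the only O(n_segments)-with-exp operation in
// a Metropolis-Hastings sweep, so it is fused here; baseline-rate updates
// reuse the returned loads.
// [[Rcpp::export]]
NumericVector cox_interval_loads(IntegerVector seg_k, NumericVector seg_dur,
                                 NumericMatrix seg_X, NumericVector beta,
                                 int K) {
  const int n = seg_k.size(), p = beta.size();
  NumericVector A(K);
  const int* kk = INTEGER(seg_k);
  const double* dd = REAL(seg_dur);
  const double* X = REAL(seg_X);
  double* a = REAL(A);
  if (p == 1) {
    const double b = beta[0];
    for (int i = 0; i < n; ++i) a[kk[i] - 1] += dd[i] * std::exp(b * X[i]);
  } else {
    for (int i = 0; i < n; ++i) {
      double eta = 0.0;
      for (int j = 0; j < p; ++j) eta += X[i + (R_xlen_t)n * j] * beta[j];
      a[kk[i] - 1] += dd[i] * std::exp(eta);
    }
  }
  return A;
}
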