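#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mean over frequencies of cos(2 pi nu t_j) on the uniform grid
// t_j = t0 + j dt (j = 0..nt-1), via the Chebyshev two-term cosine
// recurrence: one cos/sin pair per frequency instead of nt transcendental
// calls. freqs in MHz, t in microseconds, so the phase is in cycles.
// [[Rcpp::export]]
NumericVector mean_cos_uniform(NumericVector freqs, double t0, double dt,
                               int nt) {
  const int n = freqs.size();
  NumericVector out(nt);
  double *acc = REAL(out);
  for (int i = 0; i < n; ++i) {
    const double w = 2.0 * M_PI * freqs[i];
    const double a = 2.0 * std::cos(w * dt);
    double c_prev = std::cos(w * (t0 - dt));
    double c_cur  = std::cos(w * t0);
    for (int j = 0; j < nt; ++j) {
      acc[j] += c_cur;
      const double c_next = a * c_cur - c_prev;
      c_prev = c_cur;
      c_cur = c_next;
    }
  }
  const double inv = 1.0 / n;
  for (int j = 0; j < nt; ++j) acc[j] *= inv;
  return out;
}

// Same average on an arbitrary time grid (used for non-uniform axes).
// [[Rcpp::export]]
NumericVector mean_cos_general(NumericVector freqs, NumericVector t) {
  const int n = freqs.size(), nt = t.size();
  NumericVector out(nt);
  for (int i = 0; i < n; ++i) {
    const double w = 2.0 * M_PI * freqs[i];
    for (int j = 0; j < nt; ++j) out[j] += std::cos(w * t[j]);
  }
  for (int j = 0; j < nt; ++j) out[j] /= n;
  return out;
}

// Weighted version: sum_k w_k cos(2 pi nu_k t_j) for binned frequency
// histograms (weights sum to 1).
// [[Rcpp::export]]
NumericVector wmean_cos_uniform(NumericVector freqs, NumericVector wts,
                                double t0, double dt, int nt) {
  const int n = freqs.size();
  NumericVector out(nt);
  double *acc = REAL(out);
  for (int i = 0; i < n; ++i) {
    const double wt_i = wts[i];
    if (wt_i == 0.0) continue;
    const double w = 2.0 * M_PI * freqs[i];
    const double a = 2.0 * std::cos(w * dt);
    double c_prev = std::cos(w * (t0 - dt));
    double c_cur  = std::cos(w * t0);
    for (int j = 0; j < nt; ++j) {
      acc[j] += wt_i * c_cur;
      const double c_next = a * c_cur - c_prev;
      c_prev = c_cur;
      c_cur = c_next;
    }
  }
  return out;
}
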