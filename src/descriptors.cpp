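#include <Rcpp.h>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Template-match counts for sample entropy: B = pairs of m-length templates
// within Chebyshev tolerance r, A = same for (m+1)-length. Pairs i < j over
// the common template index range 1..n-m; self-matches excluded by i < j.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;  // templates of length m and m+1 both start at 0..nt-1
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double diff = std::fabs(x[i + k] - x[j + k]);
        if (diff > d) d = diff;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double dd = std::max(d, std::fabs(x[i + m] - x[j + m]));
      if (dd <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

// Centered-window Hampel pass over the raw signal: local median and scaled
// MAD over a window truncated at the series edges; replacements are decided
// against the ORIGINAL samples, not sequentially against prior replacements.
// [[Rcpp::export(name = ".hampel_core")]]
List hampel_core(NumericVector x, int half, double n_sd) {
  int n = x.size();
  NumericVector out(n);
  LogicalVector mask(n);
  std::vector<double> buf;
  buf.reserve(2 * half + 1);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half);
    int hi = std::min(n - 1, i + half);
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    int w = hi - lo + 1;
    std::vector<double> tmp(buf);
    std::nth_element(tmp.begin(), tmp.begin() + w / 2, tmp.end());
    double med = tmp[w / 2];
    if (w % 2 == 0) {
      std::nth_element(tmp.begin(), tmp.begin() + w / 2 - 1, tmp.end());
      med = 0.5 * (med + tmp[w / 2 - 1]);
    }
    for (int k = 0; k < w; ++k) tmp[k] = std::fabs(buf[k] - med);
    std::nth_element(tmp.begin(), tmp.begin() + w / 2, tmp.end());
    double mad = tmp[w / 2];
    if (w % 2 == 0) {
      std::nth_element(tmp.begin(), tmp.begin() + w / 2 - 1, tmp.end());
      mad = 0.5 * (mad + tmp[w / 2 - 1]);
    }
    double sigma = 1.4826 * mad;
    if (std::fabs(x[i] - med) > n_sd * sigma) {
      out[i] = med;
      mask[i] = true;
    } else {
      out[i] = x[i];
      mask[i] = false;
    }
  }
  return List::create(_["values"] = out, _["outlier"] = mask);
}
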