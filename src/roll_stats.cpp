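#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static double sorted_median(const std::vector<double>& v, int k) {
  int mid = k / 2;
  return (k % 2 == 1) ? v[mid] : 0.5 * (v[mid - 1] + v[mid]);
}

// MAD about m for a sorted window: deviations |v_i - m| form two runs that
// are sorted when read outward from the median, so the central order
// statistics are found by a two-pointer merge in O(k).
static double mad_from_sorted(const std::vector<double>& v, int k, double m) {
  int ri = (int)(std::upper_bound(v.begin(), v.begin() + k, m) - v.begin());
  int li = ri - 1;
  int t1 = (k - 1) / 2, t2 = k / 2;
  double a = 0.0, b = 0.0;
  for (int t = 0; t <= t2; ++t) {
    double dl = (li >= 0) ? m - v[li] : R_PosInf;
    double dr = (ri < k) ? v[ri] - m : R_PosInf;
    double d;
    if (dl <= dr) { d = dl; --li; } else { d = dr; ++ri; }
    if (t == t1) a = d;
    if (t == t2) b = d;
  }
  return 0.5 * (a + b);
}

// Trailing-window median and median absolute deviation.
//
// Windows end at 1-based indices window, window + stride, ... <= n and span
// the `window` most recent samples. The MAD is taken about the window's own
// median. Returns the evaluation indices alongside both statistics.
// [[Rcpp::export]]
List roll_med_mad_cpp(NumericVector x, int window, int stride) {
  int n = x.size();
  if (window < 1 || window > n) stop("window must be in [1, length(x)]");
  if (stride < 1) stop("stride must be >= 1");
  int n_eval = 1 + (n - window) / stride;
  IntegerVector idx(n_eval);
  NumericVector med(n_eval), mad(n_eval);
  std::vector<double> buf(window);
  for (int e = 0; e < n_eval; ++e) {
    int end = window + e * stride;       // 1-based end of window
    int from = end - window;             // 0-based start
    for (int j = 0; j < window; ++j) buf[j] = x[from + j];
    std::sort(buf.begin(), buf.end());
    double m = sorted_median(buf, window);
    idx[e] = end;
    med[e] = m;
    mad[e] = mad_from_sorted(buf, window, m);
  }
  return List::create(_["idx"] = idx, _["median"] = med, _["mad"] = mad);
}

// One centered moving-average pass with truncated windows at the edges, so
// the output has the same length as the input. Long-double prefix sums keep
// the window means exact to well below 1e-12 for series of ordinary scale.
// [[Rcpp::export]]
NumericVector ma_pass_cpp(NumericVector x, int window) {
  int n = x.size();
  if (window < 1 || window % 2 == 0) stop("window must be a positive odd integer");
  if (window > n) stop("window larger than series");
  int h = (window - 1) / 2;
  std::vector<long double> pref(n + 1, 0.0L);
  for (int i = 0; i < n; ++i) pref[i + 1] = pref[i] + (long double)x[i];
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - h);
    int hi = std::min(n - 1, i + h);
    out[i] = (double)((pref[hi + 1] - pref[lo]) / (long double)(hi - lo + 1));
  }
  return out;
}
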