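#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Type-7 (linear interpolation) quantile of a sorted vector.
static inline double q7(const std::vector<double>& s, double p) {
  const int m = (int)s.size();
  if (m == 1) return s[0];
  const double h = (m - 1) * p;
  const int lo = (int)h;
  const double g = h - lo;
  return s[lo] + g * (s[lo + 1] - s[lo]);
}

// Quantile-contrast statistic from the sorted halves of a window.
// Both halves contain the centre sample; the range is over their union.
static inline double eta_from(const std::vector<double>& L,
                              const std::vector<double>& R) {
  const double mn = std::min(L.front(), R.front());
  const double mx = std::max(L.back(), R.back());
  const double range = mx - mn;
  if (range == 0.0) return 0.0;
  double acc = 0.0;
  static const double ps[3] = {0.25, 0.5, 0.75};
  for (int j = 0; j < 3; ++j) {
    const double d = q7(L, ps[j]) - q7(R, ps[j]);
    acc += d * d;
  }
  return acc / (3.0 * range * range);
}

static inline void rm_sorted(std::vector<double>& v, double x) {
  v.erase(std::lower_bound(v.begin(), v.end(), x));
}
static inline void ins_sorted(std::vector<double>& v, double x) {
  v.insert(std::upper_bound(v.begin(), v.end(), x), x);
}

// Eta at every index for one window half-width w. Near the series ends the
// half-width shrinks to min(w, i, n-1-i). The interior is computed with
// sliding sorted windows (O(w) per shift); the two edge zones are sorted
// from scratch, which is cheap because they only span w samples each.
// [[Rcpp::export]]
NumericVector eta_scan_cpp(NumericVector y, int w) {
  const int n = y.size();
  NumericVector out(n);
  if (n == 0) return out;
  std::vector<double> L, R;

  auto brute = [&](int i) {
    const int we = std::min(w, std::min(i, n - 1 - i));
    L.assign(y.begin() + (i - we), y.begin() + i + 1);
    R.assign(y.begin() + i, y.begin() + (i + we) + 1);
    std::sort(L.begin(), L.end());
    std::sort(R.begin(), R.end());
    return eta_from(L, R);
  };

  const int lo = w, hi = n - 1 - w;
  if (lo > hi) {
    for (int i = 0; i < n; ++i) out[i] = brute(i);
    return out;
  }
  for (int i = 0; i < lo; ++i) out[i] = brute(i);
  for (int i = hi + 1; i < n; ++i) out[i] = brute(i);

  L.assign(y.begin() + (lo - w), y.begin() + lo + 1);
  R.assign(y.begin() + lo, y.begin() + lo + w + 1);
  std::sort(L.begin(), L.end());
  std::sort(R.begin(), R.end());
  out[lo] = eta_from(L, R);
  for (int i = lo + 1; i <= hi; ++i) {
    rm_sorted(L, y[i - 1 - w]);
    ins_sorted(L, y[i]);
    rm_sorted(R, y[i - 1]);
    ins_sorted(R, y[i + w]);
    out[i] = eta_from(L, R);
    if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
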