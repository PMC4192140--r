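#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Direct evaluation of the weighted intra-class variance of histogram bins
// (a, b] (0-based prefix convention): weight/N times the class variance,
// each computed from the raw counts in two passes.
static double class_var(const NumericVector& cnt, const NumericVector& mids,
                        int a, int b, double n) {
  double w = 0.0, s = 0.0;
  for (int t = a; t < b; ++t) { w += cnt[t]; s += cnt[t] * mids[t]; }
  if (w <= 0.0) return -1.0;   // empty class marker
  double mu = s / w, v = 0.0;
  for (int t = a; t < b; ++t)
    v += cnt[t] * (mids[t] - mu) * (mids[t] - mu);
  return (w / n) * (v / w);
}

// Exhaustive minimiser of the summed weighted intra-class variance over all
// 2- or 3-class contiguous partitions; ties resolved towards the smallest
// cut indices. Returns 1-based cut bin indices (cut i = classes split after
// bin i), or -1 when no valid partition exists.
// [[Rcpp::export(name = ".otsuBruteCpp")]]
IntegerVector otsu_brute_cpp(NumericVector cnt, NumericVector mids,
                             int classes) {
  const int nb = cnt.size();
  double n = 0.0;
  for (int t = 0; t < nb; ++t) n += cnt[t];
  double best = std::numeric_limits<double>::infinity();
  if (classes == 2) {
    int bi = -1;
    for (int i = 1; i < nb; ++i) {
      double a = class_var(cnt, mids, 0, i, n);
      if (a < 0) continue;
      double b = class_var(cnt, mids, i, nb, n);
      if (b < 0) continue;
      if (a + b < best) { best = a + b; bi = i; }
    }
    return IntegerVector::create(bi);
  }
  int bi = -1, bj = -1;
  for (int i = 1; i < nb - 1; ++i) {
    double a = class_var(cnt, mids, 0, i, n);
    if (a < 0) continue;
    for (int j = i + 1; j < nb; ++j) {
      double m = class_var(cnt, mids, i, j, n);
      if (m < 0) continue;
      double c = class_var(cnt, mids, j, nb, n);
      if (c < 0) continue;
      if (a + m + c < best) { best = a + m + c; bi = i; bj = j; }
    }
  }
  return IntegerVector::create(bi, bj);
}
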