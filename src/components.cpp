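#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Connected-component labelling of a 3D logical array, 26-connectivity.
// Labels are 1..K in scan order of each component's first voxel.
// [[Rcpp::export(name = ".labelComponents26Cpp")]]
IntegerVector label_components_26_cpp(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  const R_xlen_t n = s3 * n3;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;

  for (R_xlen_t p0 = 0; p0 < n; ++p0) {
    if (!mask[p0] || lab[p0]) continue;
    ++next;
    lab[p0] = next;
    stack.push_back(p0);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int i = (int)(p % n1), j = (int)((p / s2) % n2), k = (int)(p / s3);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                kk < 0 || kk >= n3)
              continue;
            R_xlen_t q = ii + jj * s2 + kk * s3;
            if (mask[q] && !lab[q]) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
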