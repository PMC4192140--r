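#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// One separable pass along the given axis (1, 2 or 3) with a normalised
// Gaussian kernel, reflected boundary.
static void blur_axis(std::vector<double>& a, int n1, int n2, int n3,
                      int axis, const std::vector<double>& ker) {
  int rad = ((int)ker.size() - 1) / 2;
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  int len = axis == 1 ? n1 : (axis == 2 ? n2 : n3);
  R_xlen_t stride = axis == 1 ? 1 : (axis == 2 ? s2 : s3);
  std::vector<double> line(len);

  int oa = axis == 1 ? n2 : n1;
  int ob = axis == 3 ? n2 : n3;
  for (int b = 0; b < ob; ++b)
    for (int aX = 0; aX < oa; ++aX) {
      R_xlen_t base;
      if (axis == 1) base = (R_xlen_t)aX * s2 + (R_xlen_t)b * s3;
      else if (axis == 2) base = (R_xlen_t)aX + (R_xlen_t)b * s3;
      else base = (R_xlen_t)aX + (R_xlen_t)b * s2;
      for (int t = 0; t < len; ++t) line[t] = a[base + t * stride];
      for (int t = 0; t < len; ++t) {
        double acc = 0.0;
        for (int u = -rad; u <= rad; ++u) {
          int s = t + u;
          if (s < 0) s = -s - 1;           // reflect
          if (s >= len) s = 2 * len - s - 1;
          acc += ker[u + rad] * line[s];
        }
        a[base + t * stride] = acc;
      }
    }
}

// Separable 3D Gaussian blur, sigma in voxel units (kernel radius 3*sigma).
// [[Rcpp::export(name = ".gaussianBlur3dCpp")]]
NumericVector gaussian_blur_3d_cpp(NumericVector vol, IntegerVector dims,
                                   double sigma) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out = clone(vol);
  if (sigma <= 0) { out.attr("dim") = dims; return out; }

  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double s = 0.0;
  for (int u = -rad; u <= rad; ++u) {
    ker[u + rad] = std::exp(-0.5 * u * u / (sigma * sigma));
    s += ker[u + rad];
  }
  for (size_t t = 0; t < ker.size(); ++t) ker[t] /= s;

  std::vector<double> a(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = out[i];
  blur_axis(a, n1, n2, n3, 1, ker);
  blur_axis(a, n1, n2, n3, 2, ker);
  blur_axis(a, n1, n2, n3, 3, ker);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = a[i];
  out.attr("dim") = dims;
  return out;
}
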