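#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double DT_INF = std::numeric_limits<double>::max() / 4.0;

// Felzenszwalb & Huttenlocher 1D squared distance transform (lower envelope
// of parabolas). f holds input squared distances, d receives the transform.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance from every voxel to the nearest
// background (FALSE) voxel. When outside_background is set, voxels outside
// the grid count as background: the grid is padded by one background layer
// (the nearest outside voxel to any interior voxel is its projection onto
// the nearest face, which lies in that layer) and cropped afterwards.
// mask is a logical 3D array (column-major, dims d1 x d2 x d3).
// [[Rcpp::export(name = ".edtSquaredCpp")]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dims,
                              bool outside_background) {
  const int pad = outside_background ? 1 : 0;
  const int n1 = dims[0] + 2 * pad, n2 = dims[1] + 2 * pad,
            n3 = dims[2] + 2 * pad;
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> buf(n, 0.0);

  // initialise: 0 at background (and pad), INF at foreground
  {
    R_xlen_t src = 0;
    for (int k = 0; k < dims[2]; ++k)
      for (int j = 0; j < dims[1]; ++j) {
        R_xlen_t dst = (R_xlen_t)(pad) +
                       (R_xlen_t)(j + pad) * n1 +
                       (R_xlen_t)(k + pad) * n1 * n2;
        for (int i = 0; i < dims[0]; ++i, ++src)
          buf[dst + i] = mask[src] ? DT_INF : 0.0;
      }
  }

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)j * n1 + (R_xlen_t)k * n1 * n2;
      for (int i = 0; i < n1; ++i) f[i] = buf[base + i];
      dt1d(f, d, v, z, n1);
      for (int i = 0; i < n1; ++i) buf[base + i] = d[i];
    }
  // axis 2 (stride n1)
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)k * n1 * n2;
      for (int j = 0; j < n2; ++j) f[j] = buf[base + (R_xlen_t)j * n1];
      dt1d(f, d, v, z, n2);
      for (int j = 0; j < n2; ++j) buf[base + (R_xlen_t)j * n1] = d[j];
    }
  // axis 3 (stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)j * n1;
      for (int k = 0; k < n3; ++k) f[k] = buf[base + (R_xlen_t)k * s3];
      dt1d(f, d, v, z, n3);
      for (int k = 0; k < n3; ++k) buf[base + (R_xlen_t)k * s3] = d[k];
    }

  NumericVector out((R_xlen_t)dims[0] * dims[1] * dims[2]);
  {
    R_xlen_t dst = 0;
    for (int k = 0; k < dims[2]; ++k)
      for (int j = 0; j < dims[1]; ++j) {
        R_xlen_t src = (R_xlen_t)(pad) +
                       (R_xlen_t)(j + pad) * n1 +
                       (R_xlen_t)(k + pad) * n1 * n2;
        for (int i = 0; i < dims[0]; ++i, ++dst)
          out[dst] = buf[src + i];
      }
  }
  out.attr("dim") = dims;
  return out;
}
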