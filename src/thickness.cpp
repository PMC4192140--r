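#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dims,
                              bool outside_background);

// Local thickness by maximal inscribed spheres (distance ridge + sphere
// painting). For every mask voxel p,
//   thickness(p) = 2 * max{ r(c) : c in mask, |p - c| < r(c) },
// where r(c) is the exact Euclidean distance from c to the nearest
// background voxel (voxels outside the grid are background). A centre c is
// skipped when some 26-neighbour q satisfies r(q) >= r(c) + |pq|: its sphere
// then lies entirely inside q's, so the maximum is unaffected.
// Result in voxel units; 0 outside the mask.
// [[Rcpp::export(name = ".localThicknessCpp")]]
NumericVector local_thickness_cpp(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  const R_xlen_t n = s3 * n3;

  NumericVector d2 = edt_squared_cpp(mask, dims, true);
  std::vector<double> r(n, 0.0);
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i]) r[i] = std::sqrt(d2[i]);

  NumericVector out(n);

  // collect unpruned (ridge) centres
  std::vector<R_xlen_t> ridge;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t p = i + j * s2 + k * s3;
        if (!mask[p]) continue;
        bool pruned = false;
        double rp = r[p];
        for (int dk = -1; dk <= 1 && !pruned; ++dk)
          for (int dj = -1; dj <= 1 && !pruned; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj && !dk) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                  kk < 0 || kk >= n3)
                continue;
              R_xlen_t q = ii + jj * s2 + kk * s3;
              if (!mask[q]) continue;
              double dpq = std::sqrt((double)(di * di + dj * dj + dk * dk));
              if (r[q] >= rp + dpq + 1e-9) { pruned = true; break; }
            }
        if (!pruned) ridge.push_back(p);
      }

  // paint each ridge sphere
  for (size_t m = 0; m < ridge.size(); ++m) {
    R_xlen_t c = ridge[m];
    int ci = (int)(c % n1);
    int cj = (int)((c / s2) % n2);
    int ck = (int)(c / s3);
    double rc = r[c], rc2 = d2[c], diam = 2.0 * rc;
    int rad = (int)std::ceil(rc);
    int k0 = std::max(0, ck - rad), k1 = std::min(n3 - 1, ck + rad);
    int j0 = std::max(0, cj - rad), j1 = std::min(n2 - 1, cj + rad);
    int i0 = std::max(0, ci - rad), i1 = std::min(n1 - 1, ci + rad);
    for (int k = k0; k <= k1; ++k) {
      double zk = (double)(k - ck) * (k - ck);
      for (int j = j0; j <= j1; ++j) {
        double zj = zk + (double)(j - cj) * (j - cj);
        if (zj >= rc2) continue;
        R_xlen_t base = (R_xlen_t)j * s2 + (R_xlen_t)k * s3;
        for (int i = i0; i <= i1; ++i) {
          double z = zj + (double)(i - ci) * (i - ci);
          if (z < rc2) {
            R_xlen_t p = base + i;
            if (mask[p] && out[p] < diam) out[p] = diam;
          }
        }
      }
    }
  }

  out.attr("dim") = dims;
  return out;
}

// Exhaustive maximal-inscribed-sphere reference: independent of the
// EDT/ridge path above. Quadratic in mask size; for small test shapes only.
// [[Rcpp::export(name = ".localThicknessBruteCpp")]]
NumericVector local_thickness_brute_cpp(LogicalVector mask,
                                        IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  const R_xlen_t n = s3 * n3;

  std::vector<int> fi, fj, fk;   // foreground
  std::vector<int> bi, bj, bk;   // background
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        if (mask[i + j * s2 + k * s3]) {
          fi.push_back(i); fj.push_back(j); fk.push_back(k);
        } else {
          bi.push_back(i); bj.push_back(j); bk.push_back(k);
        }
      }
  const size_t nf = fi.size(), nb = bi.size();

  // exhaustive squared distance to background (grid border included)
  std::vector<double> r2(nf);
  for (size_t a = 0; a < nf; ++a) {
    int i = fi[a], j = fj[a], k = fk[a];
    double border = (double)std::min(std::min(i + 1, n1 - i),
                     std::min(std::min(j + 1, n2 - j),
                              std::min(k + 1, n3 - k)));
    double best = border * border;
    for (size_t b = 0; b < nb; ++b) {
      double di = i - bi[b], dj = j - bj[b], dk = k - bk[b];
      double d = di * di + dj * dj + dk * dk;
      if (d < best) best = d;
    }
    r2[a] = best;
  }

  NumericVector out(n);
  for (size_t a = 0; a < nf; ++a) {
    double best = 0.0;
    for (size_t c = 0; c < nf; ++c) {
      double di = fi[a] - fi[c], dj = fj[a] - fj[c], dk = fk[a] - fk[c];
      if (di * di + dj * dj + dk * dk < r2[c] && r2[c] > best)
        best = r2[c];
    }
    out[fi[a] + fj[a] * s2 + fk[a] * s3] = 2.0 * std::sqrt(best);
  }
  out.attr("dim") = dims;
  return out;
}
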