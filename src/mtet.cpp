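#include <Rcpp.h>
#include <vector>
#include <map>
#include <utility>
#include <cmath>

using namespace Rcpp;

// Marching tetrahedra over the Kuhn 6-tetrahedron cube decomposition.
// The same decomposition is used in every cell, so shared cube faces carry
// matching diagonals and the extracted level surface is closed whenever the
// field is below the level on the grid boundary. Vertices are interpolated
// on cell edges and de-duplicated, triangles oriented with outward normals
// (pointing from values >= level towards values < level).

struct MTState {
  std::vector<double> vx, vy, vz;
  std::vector<int> t0, t1, t2;
  std::map<std::pair<R_xlen_t, R_xlen_t>, int> edgeVertex;
};

static int edge_point(MTState& st, const NumericVector& f,
                      R_xlen_t ia, R_xlen_t ib,
                      double xa, double ya, double za,
                      double xb, double yb, double zb, double level) {
  std::pair<R_xlen_t, R_xlen_t> key =
      ia < ib ? std::make_pair(ia, ib) : std::make_pair(ib, ia);
  std::map<std::pair<R_xlen_t, R_xlen_t>, int>::iterator it =
      st.edgeVertex.find(key);
  if (it != st.edgeVertex.end()) return it->second;
  double fa = f[ia], fb = f[ib];
  double t = (level - fa) / (fb - fa);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  st.vx.push_back(xa + t * (xb - xa));
  st.vy.push_back(ya + t * (yb - ya));
  st.vz.push_back(za + t * (zb - za));
  int id = (int)st.vx.size() - 1;
  st.edgeVertex[key] = id;
  return id;
}

static void add_tri(MTState& st, int a, int b, int c,
                    double ix, double iy, double iz) {
  // orient so the normal points away from the inside reference point
  double ax = st.vx[a], ay = st.vy[a], az = st.vz[a];
  double ux = st.vx[b] - ax, uy = st.vy[b] - ay, uz = st.vz[b] - az;
  double wx = st.vx[c] - ax, wy = st.vy[c] - ay, wz = st.vz[c] - az;
  double nx = uy * wz - uz * wy;
  double ny = uz * wx - ux * wz;
  double nz = ux * wy - uy * wx;
  double cx = (ax + st.vx[b] + st.vx[c]) / 3.0 - ix;
  double cy = (ay + st.vy[b] + st.vy[c]) / 3.0 - iy;
  double cz = (az + st.vz[b] + st.vz[c]) / 3.0 - iz;
  if (nx * cx + ny * cy + nz * cz < 0) { int tmp = b; b = c; c = tmp; }
  st.t0.push_back(a);
  st.t1.push_back(b);
  st.t2.push_back(c);
}

// [[Rcpp::export(name = ".marchingTetrahedraCpp")]]
List marching_tetrahedra_cpp(NumericVector field, IntegerVector dims,
                             double level) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2;
  MTState st;

  // Kuhn decomposition: one tetrahedron per permutation of the unit steps
  static const int perms[6][3] = {
    {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  const int step[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};

  for (int k = 0; k + 1 < n3; ++k)
    for (int j = 0; j + 1 < n2; ++j)
      for (int i = 0; i + 1 < n1; ++i) {
        for (int pm = 0; pm < 6; ++pm) {
          int ci[4] = {i, 0, 0, 0}, cj[4] = {j, 0, 0, 0}, ck[4] = {k, 0, 0, 0};
          for (int v = 1; v < 4; ++v) {
            const int* d = step[perms[pm][v - 1]];
            ci[v] = ci[v - 1] + d[0];
            cj[v] = cj[v - 1] + d[1];
            ck[v] = ck[v - 1] + d[2];
          }
          R_xlen_t idx[4];
          bool inside[4];
          int nin = 0;
          for (int v = 0; v < 4; ++v) {
            idx[v] = ci[v] + (R_xlen_t)cj[v] * s2 + (R_xlen_t)ck[v] * s3;
            inside[v] = field[idx[v]] >= level;
            if (inside[v]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;

          int in[4], out[4], ni = 0, no = 0;
          for (int v = 0; v < 4; ++v)
            if (inside[v]) in[ni++] = v; else out[no++] = v;

          if (nin == 1 || nin == 3) {
            int a = nin == 1 ? in[0] : out[0];
            const int* oth = nin == 1 ? out : in;
            int p[3];
            for (int v = 0; v < 3; ++v)
              p[v] = edge_point(st, field, idx[a], idx[oth[v]],
                                ci[a], cj[a], ck[a],
                                ci[oth[v]], cj[oth[v]], ck[oth[v]], level);
            int ref = nin == 1 ? a : in[0];
            add_tri(st, p[0], p[1], p[2], ci[ref], cj[ref], ck[ref]);
          } else {                       // 2 in, 2 out -> quad
            int a = in[0], b = in[1], c = out[0], d = out[1];
            int pac = edge_point(st, field, idx[a], idx[c], ci[a], cj[a],
                                 ck[a], ci[c], cj[c], ck[c], level);
            int pad = edge_point(st, field, idx[a], idx[d], ci[a], cj[a],
                                 ck[a], ci[d], cj[d], ck[d], level);
            int pbc = edge_point(st, field, idx[b], idx[c], ci[b], cj[b],
                                 ck[b], ci[c], cj[c], ck[c], level);
            int pbd = edge_point(st, field, idx[b], idx[d], ci[b], cj[b],
                                 ck[b], ci[d], cj[d], ck[d], level);
            double ix = 0.5 * (ci[a] + ci[b]);
            double iy = 0.5 * (cj[a] + cj[b]);
            double iz = 0.5 * (ck[a] + ck[b]);
            add_tri(st, pac, pad, pbd, ix, iy, iz);
            add_tri(st, pac, pbd, pbc, ix, iy, iz);
          }
        }
      }

  int nv = (int)st.vx.size(), nt = (int)st.t0.size();
  NumericMatrix verts(nv, 3);
  for (int v = 0; v < nv; ++v) {
    verts(v, 0) = st.vx[v];
    verts(v, 1) = st.vy[v];
    verts(v, 2) = st.vz[v];
  }
  IntegerMatrix tris(nt, 3);
  for (int t = 0; t < nt; ++t) {
    tris(t, 0) = st.t0[t] + 1;
    tris(t, 1) = st.t1[t] + 1;
    tris(t, 2) = st.t2[t] + 1;
  }
  return List::create(Named("vertices") = verts, Named("faces") = tris);
}
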