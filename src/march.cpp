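// Iso-surface extraction by marching tetrahedra on the 6-tetrahedron Kuhn
// decomposition of each grid cube (all cubes share the same main diagonal, so
// face diagonals of adjacent cubes agree and the output surface is closed
// whenever the grid boundary lies outside the object). Vertices are placed by
// linear interpolation along tetrahedron edges and welded via grid-edge keys.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// corner index = cx + 2*cy + 4*cz; Kuhn tets, each containing diagonal 0-7
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
};

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  uint64_t ng;
  double iso;

  int edge_point(uint64_t gA, uint64_t gB, double va, double vb,
                 const double* pa, const double* pb) {
    uint64_t g1 = gA, g2 = gB;
    double v1 = va, v2 = vb;
    const double *p1 = pa, *p2 = pb;
    if (g2 < g1) { std::swap(g1, g2); std::swap(v1, v2); std::swap(p1, p2); }
    uint64_t key = g1 * ng + g2;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - v1) / (v2 - v1);
    int id = (int)vx.size();
    vx.push_back(p1[0] + t * (p2[0] - p1[0]));
    vy.push_back(p1[1] + t * (p2[1] - p1[1]));
    vz.push_back(p1[2] + t * (p2[2] - p1[2]));
    edge_vertex[key] = id;
    return id;
  }

  void emit(int a, int b, int c, const double* dir) {
    // orient so the normal points from inside (>= iso) to outside
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
    if (nx * dir[0] + ny * dir[1] + nz * dir[2] < 0) std::swap(b, c);
    f0.push_back(a); f1.push_back(b); f2.push_back(c);
  }
};

// [[Rcpp::export]]
List cpp_marching_tets(const NumericVector& vol, const IntegerVector& dim,
                       const NumericVector& spacing, const NumericVector& origin,
                       double iso) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const double x0 = origin[0], y0 = origin[1], z0 = origin[2];
  const double eps = 1e-9 * (std::fabs(iso) + 1.0);

  MTState st;
  st.ng = (uint64_t)nz * ny * nx;
  st.iso = iso;

  double cv[8];     // corner values (perturbed off the iso level)
  double cp[8][3];  // corner positions
  uint64_t cg[8];   // corner global grid ids
  bool cin[8];

  for (int k = 0; k < nx - 1; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      R_xlen_t base = (R_xlen_t)nz * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nz - 1; ++i) {
        int n_in = 0;
        for (int c = 0; c < 8; ++c) {
          int cx = c & 1, cy = (c >> 1) & 1, cz = (c >> 2) & 1;
          int ii = i + cz, jj = j + cy, kk = k + cx;
          double v = vol[(R_xlen_t)ii + (R_xlen_t)nz * (jj + (R_xlen_t)ny * kk)];
          if (v == iso) v += eps;
          cv[c] = v;
          cin[c] = v >= iso;
          if (cin[c]) ++n_in;
          cg[c] = (uint64_t)ii + (uint64_t)nz * ((uint64_t)jj + (uint64_t)ny * kk);
          cp[c][0] = x0 + kk * dx; cp[c][1] = y0 + jj * dy; cp[c][2] = z0 + ii * dz;
        }
        if (n_in == 0 || n_in == 8) continue;

        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int in_idx[4], out_idx[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (cin[T[c]]) in_idx[ni++] = T[c]; else out_idx[no++] = T[c];
          }
          if (ni == 0 || ni == 4) continue;
          double dir[3];
          double ci[3] = {0, 0, 0}, co[3] = {0, 0, 0};
          for (int c = 0; c < ni; ++c)
            for (int a = 0; a < 3; ++a) ci[a] += cp[in_idx[c]][a] / ni;
          for (int c = 0; c < no; ++c)
            for (int a = 0; a < 3; ++a) co[a] += cp[out_idx[c]][a] / no;
          for (int a = 0; a < 3; ++a) dir[a] = co[a] - ci[a];

          auto ep = [&](int A, int B) {
            return st.edge_point(cg[A], cg[B], cv[A], cv[B], cp[A], cp[B]);
          };
          if (ni == 1) {
            int A = in_idx[0];
            st.emit(ep(A, out_idx[0]), ep(A, out_idx[1]), ep(A, out_idx[2]), dir);
          } else if (ni == 3) {
            int D = out_idx[0];
            st.emit(ep(in_idx[0], D), ep(in_idx[1], D), ep(in_idx[2], D), dir);
          } else { // 2-2: quad across edges AC, AD, BD, BC
            int A = in_idx[0], B = in_idx[1], C = out_idx[0], D = out_idx[1];
            int q0 = ep(A, C), q1 = ep(A, D), q2 = ep(B, D), q3 = ep(B, C);
            st.emit(q0, q1, q2, dir);
            st.emit(q0, q2, q3, dir);
          }
        }
      }
    }
  }

  int nv = (int)st.vx.size(), nf = (int)st.f0.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i]; }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) { F(i, 0) = st.f0[i]; F(i, 1) = st.f1[i]; F(i, 2) = st.f2[i]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
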