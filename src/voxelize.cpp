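// Occupancy voxelization of a watertight mesh: each voxel column is probed by
// nsub x nsub vertical sub-rays; inside intervals along z are obtained from
// ray/triangle crossing parity and integrated exactly over each voxel's z
// extent (through-slice averaging). Returns per-voxel occupancy in [0, 1].
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_voxelize(const NumericMatrix& V, const IntegerMatrix& F,
                  const IntegerVector& dim, const NumericVector& spacing,
                  const NumericVector& origin, int nsub) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const double x0 = origin[0], y0 = origin[1], z0 = origin[2];
  const double xlo = x0 - 0.5 * dx, ylo = y0 - 0.5 * dy, zlo = z0 - 0.5 * dz;
  const int m = F.nrow();

  // bin triangles into voxel columns by xy bounding box
  std::vector<std::vector<int>> bins((size_t)nx * ny);
  for (int f = 0; f < m; ++f) {
    double minx = R_PosInf, maxx = R_NegInf, miny = R_PosInf, maxy = R_NegInf;
    for (int e = 0; e < 3; ++e) {
      double px = V(F(f, e), 0), py = V(F(f, e), 1);
      minx = std::min(minx, px); maxx = std::max(maxx, px);
      miny = std::min(miny, py); maxy = std::max(maxy, py);
    }
    int k0 = std::max(0, (int)std::floor((minx - xlo) / dx));
    int k1 = std::min(nx - 1, (int)std::floor((maxx - xlo) / dx));
    int j0 = std::max(0, (int)std::floor((miny - ylo) / dy));
    int j1 = std::min(ny - 1, (int)std::floor((maxy - ylo) / dy));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        bins[(size_t)k * ny + j].push_back(f);
  }

  NumericVector occ((R_xlen_t)nz * ny * nx); // filled with 0
  const double sub = 1.0 / nsub;
  // fixed irrational jitter keeps sub-rays off triangle edges in projection
  const double jx = 1.1920928955078125e-4 * dx * 0.7548776662466927;
  const double jy = 1.1920928955078125e-4 * dy * 0.5698402909980532;
  int odd_rays = 0;
  std::vector<double> zhits;

  for (int k = 0; k < nx; ++k) {
    for (int j = 0; j < ny; ++j) {
      const std::vector<int>& tris = bins[(size_t)k * ny + j];
      if (tris.empty()) continue;
      for (int sx = 0; sx < nsub; ++sx) {
        for (int sy = 0; sy < nsub; ++sy) {
          double px = xlo + (k + (sx + 0.5) * sub) * dx + jx;
          double py = ylo + (j + (sy + 0.5) * sub) * dy + jy;
          zhits.clear();
          for (int t : tris) {
            double ax = V(F(t, 0), 0), ay = V(F(t, 0), 1), az = V(F(t, 0), 2);
            double bx = V(F(t, 1), 0), by = V(F(t, 1), 1), bz = V(F(t, 1), 2);
            double cx = V(F(t, 2), 0), cy = V(F(t, 2), 1), cz = V(F(t, 2), 2);
            double d00x = bx - ax, d00y = by - ay;
            double d01x = cx - ax, d01y = cy - ay;
            double det = d00x * d01y - d01x * d00y;
            if (std::fabs(det) < 1e-300) continue; // degenerate in projection
            double qx = px - ax, qy = py - ay;
            double u = (qx * d01y - d01x * qy) / det;
            if (u < 0.0 || u > 1.0) continue;
            double v = (d00x * qy - qx * d00y) / det;
            if (v < 0.0 || u + v > 1.0) continue;
            zhits.push_back(az + u * (bz - az) + v * (cz - az));
          }
          if (zhits.empty()) continue;
          if (zhits.size() % 2 == 1) { ++odd_rays; continue; }
          std::sort(zhits.begin(), zhits.end());
          for (size_t h = 0; h + 1 < zhits.size(); h += 2) {
            double za = zhits[h], zb = zhits[h + 1];
            if (zb <= za) continue;
            int i0 = std::max(0, (int)std::floor((za - zlo) / dz));
            int i1 = std::min(nz - 1, (int)std::floor((zb - zlo) / dz));
            for (int i = i0; i <= i1; ++i) {
              double cell_lo = zlo + i * dz, cell_hi = cell_lo + dz;
              double ov = std::min(zb, cell_hi) - std::max(za, cell_lo);
              if (ov > 0)
                occ[(R_xlen_t)i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k)] += ov / dz;
            }
          }
        }
      }
    }
  }
  double norm = sub * sub;
  for (R_xlen_t i = 0; i < occ.size(); ++i) occ[i] *= norm;
  occ.attr("dim") = dim;
  return List::create(_["occupancy"] = occ, _["odd_rays"] = odd_rays);
}
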