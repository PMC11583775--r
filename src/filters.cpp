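// Separable Gaussian blur, true 3D median filter and a 2D exact Euclidean
// distance transform, all operating on (slice, row, col)-indexed grids.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static void blur_axis(std::vector<double>& a, int n0, int n1, int n2,
                      int axis, double sigma) {
  // dims: (n0, n1, n2) with linear index i0 + n0*(i1 + n1*i2)
  if (sigma <= 0) return;
  int r = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> w(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { w[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += w[i + r]; }
  for (double& x : w) x /= s;
  int len = axis == 0 ? n0 : (axis == 1 ? n1 : n2);
  std::vector<double> line(len), out(len);
  int stride = axis == 0 ? 1 : (axis == 1 ? n0 : n0 * n1);
  int nlines0 = axis == 0 ? n1 : n0;
  int nlines1 = axis == 2 ? n1 : n2;
  for (int b = 0; b < nlines1; ++b) {
    for (int a2 = 0; a2 < nlines0; ++a2) {
      R_xlen_t base;
      if (axis == 0)      base = (R_xlen_t)n0 * (a2 + (R_xlen_t)n1 * b);
      else if (axis == 1) base = a2 + (R_xlen_t)n0 * n1 * b;
      else                base = a2 + (R_xlen_t)n0 * b;
      for (int i = 0; i < len; ++i) line[i] = a[base + (R_xlen_t)i * stride];
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int t = -r; t <= r; ++t) {
          int idx = i + t;
          if (idx < 0) idx = 0; else if (idx >= len) idx = len - 1; // replicate
          acc += w[t + r] * line[idx];
        }
        out[i] = acc;
      }
      for (int i = 0; i < len; ++i) a[base + (R_xlen_t)i * stride] = out[i];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(const NumericVector& vol, const IntegerVector& dim,
                              const NumericVector& sigma_vox) {
  int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  std::vector<double> a(vol.begin(), vol.end());
  blur_axis(a, n0, n1, n2, 0, sigma_vox[0]);
  blur_axis(a, n0, n1, n2, 1, sigma_vox[1]);
  blur_axis(a, n0, n1, n2, 2, sigma_vox[2]);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// True median over an odd box window (w0, w1, w2); windows are clipped at the
// grid boundary, so the border median is taken over the in-bounds voxels.
// [[Rcpp::export]]
NumericVector cpp_median_filter3(const NumericVector& vol, const IntegerVector& dim,
                                 const IntegerVector& w) {
  int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  int r0 = w[0] / 2, r1 = w[1] / 2, r2 = w[2] / 2;
  NumericVector out((R_xlen_t)n0 * n1 * n2);
  std::vector<double> buf;
  buf.reserve((size_t)w[0] * w[1] * w[2]);
  for (int k = 0; k < n2; ++k) {
    int k0 = std::max(0, k - r2), k1 = std::min(n2 - 1, k + r2);
    for (int j = 0; j < n1; ++j) {
      int j0 = std::max(0, j - r1), j1 = std::min(n1 - 1, j + r1);
      for (int i = 0; i < n0; ++i) {
        int i0 = std::max(0, i - r0), i1 = std::min(n0 - 1, i + r0);
        buf.clear();
        for (int kk = k0; kk <= k1; ++kk)
          for (int jj = j0; jj <= j1; ++jj) {
            R_xlen_t base = (R_xlen_t)n0 * (jj + (R_xlen_t)n1 * kk);
            for (int ii = i0; ii <= i1; ++ii) buf.push_back(vol[base + ii]);
          }
        size_t nb = buf.size();
        size_t mid = nb / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        double med = buf[mid];
        if (nb % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + mid);
          med = 0.5 * (med + lo);
        }
        out[(R_xlen_t)i + (R_xlen_t)n0 * (j + (R_xlen_t)n1 * k)] = med;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Felzenszwalb & Huttenlocher exact 1D squared distance transform
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -R_PosInf; z[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Distance (in pixels) from each foreground pixel to the nearest background
// pixel of a 2D mask; 0 on background.
// [[Rcpp::export]]
NumericMatrix cpp_edt2d(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double LARGE = 1e15; // farther than any in-grid squared distance
  std::vector<double> g((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      g[(size_t)j * nr + i] = mask(i, j) ? LARGE : 0.0;
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // columns
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = g[(size_t)j * nr + i];
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) g[(size_t)j * nr + i] = std::min(d[i], LARGE);
  }
  // rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = g[(size_t)j * nr + i];
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) g[(size_t)j * nr + i] = d[j];
  }
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = std::sqrt(g[(size_t)j * nr + i]);
  return out;
}
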