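#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <functional>
using namespace Rcpp;

// Per-face signed volume contribution (divergence theorem); faces 0-based.
// [[Rcpp::export]]
NumericVector cpp_face_signed_volumes(const NumericMatrix& V, const IntegerMatrix& F) {
  int m = F.nrow();
  NumericVector out(m);
  for (int f = 0; f < m; ++f) {
    int a = F(f, 0), b = F(f, 1), c = F(f, 2);
    double ax = V(a, 0), ay = V(a, 1), az = V(a, 2);
    double bx = V(b, 0), by = V(b, 1), bz = V(b, 2);
    double cx = V(c, 0), cy = V(c, 1), cz = V(c, 2);
    out[f] = (ax * (by * cz - bz * cy)
            - ay * (bx * cz - bz * cx)
            + az * (bx * cy - by * cx)) / 6.0;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_face_areas(const NumericMatrix& V, const IntegerMatrix& F) {
  int m = F.nrow();
  NumericVector out(m);
  for (int f = 0; f < m; ++f) {
    int a = F(f, 0), b = F(f, 1), c = F(f, 2);
    double ux = V(b, 0) - V(a, 0), uy = V(b, 1) - V(a, 1), uz = V(b, 2) - V(a, 2);
    double vx = V(c, 0) - V(a, 0), vy = V(c, 1) - V(a, 1), vz = V(c, 2) - V(a, 2);
    double cx = uy * vz - uz * vy;
    double cy = uz * vx - ux * vz;
    double cz = ux * vy - uy * vx;
    out[f] = 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
  }
  return out;
}

// Edge incidence audit: counts edges and edges not shared by exactly two faces.
// An edge here is an unordered vertex pair.
// [[Rcpp::export]]
List cpp_edge_audit(const IntegerMatrix& F, int n_vertices) {
  std::unordered_map<uint64_t, int> cnt;
  cnt.reserve(F.nrow() * 3);
  uint64_t n = (uint64_t)n_vertices;
  for (int f = 0; f < F.nrow(); ++f) {
    for (int e = 0; e < 3; ++e) {
      uint64_t a = (uint64_t)F(f, e);
      uint64_t b = (uint64_t)F(f, (e + 1) % 3);
      uint64_t key = a < b ? a * n + b : b * n + a;
      ++cnt[key];
    }
  }
  int open = 0;
  for (auto& kv : cnt) if (kv.second != 2) ++open;
  return List::create(_["n_edges"] = (int)cnt.size(), _["n_open_edges"] = open);
}

// Connected components over faces (faces sharing a vertex are connected).
// Returns 1-based component label per face.
// [[Rcpp::export]]
IntegerVector cpp_face_components(const IntegerMatrix& F, int n_vertices) {
  std::vector<int> parent(n_vertices);
  for (int i = 0; i < n_vertices; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int f = 0; f < F.nrow(); ++f) {
    int a = find(F(f, 0)), b = find(F(f, 1)), c = find(F(f, 2));
    parent[b] = a; parent[c] = find(a);
  }
  std::unordered_map<int, int> label;
  IntegerVector out(F.nrow());
  int next = 0;
  for (int f = 0; f < F.nrow(); ++f) {
    int r = find(F(f, 0));
    auto it = label.find(r);
    if (it == label.end()) { label[r] = ++next; out[f] = next; }
    else out[f] = it->second;
  }
  return out;
}

// Taubin lambda/mu smoothing with uniform weights. Connectivity unchanged.
// [[Rcpp::export]]
NumericMatrix cpp_taubin_smooth(const NumericMatrix& V, const IntegerMatrix& F,
                                int iterations, double lambda, double mu) {
  int n = V.nrow();
  // adjacency (deduplicated)
  std::vector<std::vector<int>> adj(n);
  for (int f = 0; f < F.nrow(); ++f) {
    int idx[3] = {F(f, 0), F(f, 1), F(f, 2)};
    for (int e = 0; e < 3; ++e) {
      adj[idx[e]].push_back(idx[(e + 1) % 3]);
      adj[idx[e]].push_back(idx[(e + 2) % 3]);
    }
  }
  for (int i = 0; i < n; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
  }
  std::vector<double> x(n), y(n), z(n), nx(n), ny(n), nz(n);
  for (int i = 0; i < n; ++i) { x[i] = V(i, 0); y[i] = V(i, 1); z[i] = V(i, 2); }
  auto pass = [&](double w) {
    for (int i = 0; i < n; ++i) {
      if (adj[i].empty()) { nx[i] = x[i]; ny[i] = y[i]; nz[i] = z[i]; continue; }
      double mx = 0, my = 0, mz = 0;
      for (int j : adj[i]) { mx += x[j]; my += y[j]; mz += z[j]; }
      double k = 1.0 / adj[i].size();
      nx[i] = x[i] + w * (mx * k - x[i]);
      ny[i] = y[i] + w * (my * k - y[i]);
      nz[i] = z[i] + w * (mz * k - z[i]);
    }
    x.swap(nx); y.swap(ny); z.swap(nz);
  };
  for (int it = 0; it < iterations; ++it) { pass(lambda); pass(mu); }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i]; }
  return out;
}
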