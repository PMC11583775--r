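// Bounding-volume hierarchy over mesh triangles: exact closest point on the
// surface and ray-parity inside/outside classification. Built once per mesh
// and reused across queries via an external pointer.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3(double x_ = 0, double y_ = 0, double z_ = 0) : x(x_), y(y_), z(z_) {}
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};
static inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}

// Ericson, Real-Time Collision Detection: closest point on triangle abc to p.
static Vec3 closest_on_triangle(const Vec3& p, const Vec3& a, const Vec3& b, const Vec3& c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) { double v = d1 / (d1 - d3); return a + ab * v; }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) { double w = d2 / (d2 - d6); return a + ac * w; }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

struct BVHNode {
  double bmin[3], bmax[3];
  int left = -1, right = -1; // children; leaf if left < 0
  int start = 0, count = 0;  // triangle range for leaves
};

struct BVH {
  std::vector<Vec3> va, vb, vc;   // triangle vertices in build order
  std::vector<int> face_id;       // original face index per triangle slot
  std::vector<BVHNode> nodes;
  int root = -1;

  int build(std::vector<int>& idx, int start, int count,
            const std::vector<Vec3>& A, const std::vector<Vec3>& B,
            const std::vector<Vec3>& C, const std::vector<Vec3>& cent) {
    BVHNode node;
    node.bmin[0] = node.bmin[1] = node.bmin[2] = std::numeric_limits<double>::infinity();
    node.bmax[0] = node.bmax[1] = node.bmax[2] = -std::numeric_limits<double>::infinity();
    for (int i = start; i < start + count; ++i) {
      const Vec3* tri[3] = {&A[idx[i]], &B[idx[i]], &C[idx[i]]};
      for (int k = 0; k < 3; ++k) {
        const Vec3& v = *tri[k];
        node.bmin[0] = std::min(node.bmin[0], v.x); node.bmax[0] = std::max(node.bmax[0], v.x);
        node.bmin[1] = std::min(node.bmin[1], v.y); node.bmax[1] = std::max(node.bmax[1], v.y);
        node.bmin[2] = std::min(node.bmin[2], v.z); node.bmax[2] = std::max(node.bmax[2], v.z);
      }
    }
    int self = (int)nodes.size();
    nodes.push_back(node);
    if (count <= 8) {
      nodes[self].start = start;
      nodes[self].count = count;
      return self;
    }
    double ext[3] = {node.bmax[0] - node.bmin[0], node.bmax[1] - node.bmin[1],
                     node.bmax[2] - node.bmin[2]};
    int axis = 0;
    if (ext[1] > ext[axis]) axis = 1;
    if (ext[2] > ext[axis]) axis = 2;
    int mid = start + count / 2;
    std::nth_element(idx.begin() + start, idx.begin() + mid, idx.begin() + start + count,
                     [&](int a, int b) {
                       double ca = axis == 0 ? cent[a].x : (axis == 1 ? cent[a].y : cent[a].z);
                       double cb = axis == 0 ? cent[b].x : (axis == 1 ? cent[b].y : cent[b].z);
                       return ca < cb;
                     });
    int l = build(idx, start, mid - start, A, B, C, cent);
    int r = build(idx, mid, start + count - mid, A, B, C, cent);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }

  void init(const NumericMatrix& V, const IntegerMatrix& F) {
    int m = F.nrow();
    std::vector<Vec3> A(m), B(m), C(m), cent(m);
    for (int f = 0; f < m; ++f) {
      A[f] = Vec3(V(F(f, 0), 0), V(F(f, 0), 1), V(F(f, 0), 2));
      B[f] = Vec3(V(F(f, 1), 0), V(F(f, 1), 1), V(F(f, 1), 2));
      C[f] = Vec3(V(F(f, 2), 0), V(F(f, 2), 1), V(F(f, 2), 2));
      cent[f] = (A[f] + B[f] + C[f]) * (1.0 / 3.0);
    }
    std::vector<int> idx(m);
    for (int i = 0; i < m; ++i) idx[i] = i;
    nodes.reserve(2 * m / 8 + 16);
    root = build(idx, 0, m, A, B, C, cent);
    va.resize(m); vb.resize(m); vc.resize(m); face_id.resize(m);
    for (int i = 0; i < m; ++i) {
      va[i] = A[idx[i]]; vb[i] = B[idx[i]]; vc[i] = C[idx[i]];
      face_id[i] = idx[i];
    }
  }

  static double box_dist2(const BVHNode& n, const Vec3& p) {
    double d = 0;
    double c[3] = {p.x, p.y, p.z};
    for (int k = 0; k < 3; ++k) {
      double v = c[k];
      if (v < n.bmin[k]) { double e = n.bmin[k] - v; d += e * e; }
      else if (v > n.bmax[k]) { double e = v - n.bmax[k]; d += e * e; }
    }
    return d;
  }

  void closest(const Vec3& p, double& best2, Vec3& bestp, int& bestf, int ni) const {
    const BVHNode& n = nodes[ni];
    if (n.left < 0) {
      for (int i = n.start; i < n.start + n.count; ++i) {
        Vec3 q = closest_on_triangle(p, va[i], vb[i], vc[i]);
        Vec3 d = p - q;
        double d2 = dot(d, d);
        if (d2 < best2) { best2 = d2; bestp = q; bestf = face_id[i]; }
      }
      return;
    }
    double dl = box_dist2(nodes[n.left], p);
    double dr = box_dist2(nodes[n.right], p);
    int first = n.left, second = n.right;
    if (dr < dl) { std::swap(first, second); std::swap(dl, dr); }
    if (dl < best2) closest(p, best2, bestp, bestf, first);
    if (dr < best2) closest(p, best2, bestp, bestf, second);
  }

  // slab test for a ray p + t*d, t in (0, inf)
  static bool ray_hits_box(const BVHNode& n, const Vec3& p, const Vec3& inv_d) {
    double t0 = 0.0, t1 = std::numeric_limits<double>::infinity();
    double pc[3] = {p.x, p.y, p.z};
    double id[3] = {inv_d.x, inv_d.y, inv_d.z};
    for (int k = 0; k < 3; ++k) {
      double ta = (n.bmin[k] - pc[k]) * id[k];
      double tb = (n.bmax[k] - pc[k]) * id[k];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
      if (t0 > t1) return false;
    }
    return true;
  }

  // Moeller-Trumbore; counts crossings with t > eps
  void ray_count(const Vec3& p, const Vec3& d, const Vec3& inv_d, int ni, int& count) const {
    const BVHNode& n = nodes[ni];
    if (!ray_hits_box(n, p, inv_d)) return;
    if (n.left < 0) {
      for (int i = n.start; i < n.start + n.count; ++i) {
        Vec3 e1 = vb[i] - va[i], e2 = vc[i] - va[i];
        Vec3 h = cross(d, e2);
        double det = dot(e1, h);
        if (std::fabs(det) < 1e-14) continue;
        double inv = 1.0 / det;
        Vec3 s = p - va[i];
        double u = dot(s, h) * inv;
        if (u < 0.0 || u > 1.0) continue;
        Vec3 q = cross(s, e1);
        double v = dot(d, q) * inv;
        if (v < 0.0 || u + v > 1.0) continue;
        double t = dot(e2, q) * inv;
        if (t > 1e-12) ++count;
      }
      return;
    }
    ray_count(p, d, inv_d, n.left, count);
    ray_count(p, d, inv_d, n.right, count);
  }
};

// [[Rcpp::export]]
SEXP cpp_bvh_build(const NumericMatrix& V, const IntegerMatrix& F) {
  XPtr<BVH> ptr(new BVH(), true);
  ptr->init(V, F);
  return ptr;
}

// [[Rcpp::export]]
List cpp_bvh_closest(SEXP bvh_ptr, const NumericMatrix& Q) {
  XPtr<BVH> bvh(bvh_ptr);
  int n = Q.nrow();
  NumericMatrix P(n, 3);
  NumericVector dist(n);
  IntegerVector face(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p(Q(i, 0), Q(i, 1), Q(i, 2));
    double best2 = std::numeric_limits<double>::infinity();
    Vec3 bp; int bf = -1;
    bvh->closest(p, best2, bp, bf, bvh->root);
    P(i, 0) = bp.x; P(i, 1) = bp.y; P(i, 2) = bp.z;
    dist[i] = std::sqrt(best2);
    face[i] = bf + 1;
  }
  return List::create(_["point"] = P, _["distance"] = dist, _["face"] = face);
}

// [[Rcpp::export]]
LogicalVector cpp_bvh_inside(SEXP bvh_ptr, const NumericMatrix& Q) {
  XPtr<BVH> bvh(bvh_ptr);
  int n = Q.nrow();
  LogicalVector out(n);
  // fixed irrational direction: vanishing probability of hitting an edge
  Vec3 d(0.5377397215536813, 0.7370361175679103, 0.4100285257289274);
  double nrm = std::sqrt(dot(d, d));
  d = d * (1.0 / nrm);
  Vec3 inv_d(1.0 / d.x, 1.0 / d.y, 1.0 / d.z);
  for (int i = 0; i < n; ++i) {
    Vec3 p(Q(i, 0), Q(i, 1), Q(i, 2));
    int count = 0;
    bvh->ray_count(p, d, inv_d, bvh->root, count);
    out[i] = (count % 2) == 1;
  }
  return out;
}
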