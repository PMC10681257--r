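// Exact closest-point-on-surface queries for triangle meshes.
//
// A bounding-volume hierarchy (median split on the longest centroid axis)
// prunes only nodes whose axis-aligned box is provably farther than the
// current best squared distance, so every query returns the exact
// minimiser over all faces, identical to a brute-force scan.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  Vec3 r = {a.x - b.x, a.y - b.y, a.z - b.z};
  return r;
}
static inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// Closest point on triangle abc to p (Ericson, Real-Time Collision
// Detection, section 5.1.5).  Also returns barycentric coordinates
// (u, v, w) of the closest point with respect to (a, b, c).
static Vec3 closest_on_triangle(const Vec3 &p, const Vec3 &a, const Vec3 &b,
                                const Vec3 &c, double &u, double &v,
                                double &w) {
  Vec3 ab = vsub(b, a), ac = vsub(c, a), ap = vsub(p, a);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) {
    u = 1.0; v = 0.0; w = 0.0;
    return a;
  }
  Vec3 bp = vsub(p, b);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) {
    u = 0.0; v = 1.0; w = 0.0;
    return b;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double t = d1 / (d1 - d3);
    u = 1.0 - t; v = t; w = 0.0;
    Vec3 r = {a.x + t * ab.x, a.y + t * ab.y, a.z + t * ab.z};
    return r;
  }
  Vec3 cp = vsub(p, c);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) {
    u = 0.0; v = 0.0; w = 1.0;
    return c;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double t = d2 / (d2 - d6);
    u = 1.0 - t; v = 0.0; w = t;
    Vec3 r = {a.x + t * ac.x, a.y + t * ac.y, a.z + t * ac.z};
    return r;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    u = 0.0; v = 1.0 - t; w = t;
    Vec3 bc = vsub(c, b);
    Vec3 r = {b.x + t * bc.x, b.y + t * bc.y, b.z + t * bc.z};
    return r;
  }
  double denom = 1.0 / (va + vb + vc);
  double vv = vb * denom, ww = vc * denom;
  u = 1.0 - vv - ww; v = vv; w = ww;
  Vec3 r = {a.x + ab.x * vv + ac.x * ww, a.y + ab.y * vv + ac.y * ww,
            a.z + ab.z * vv + ac.z * ww};
  return r;
}

struct Node {
  double lo[3], hi[3];
  int left, right;   // children, -1 for leaf
  int start, count;  // leaf triangle range in `order`
};

struct BVH {
  std::vector<Node> nodes;
  std::vector<int> order;  // permutation of triangle ids
  const double *V;
  const int *F;  // 0-based, column-major m x 3
  int m;

  void tri_bounds(int t, double lo[3], double hi[3]) const {
    int i0 = F[t], i1 = F[t + m], i2 = F[t + 2 * m];
    const double *vs[3] = {V + 3 * i0, V + 3 * i1, V + 3 * i2};
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(vs[0][k], std::min(vs[1][k], vs[2][k]));
      hi[k] = std::max(vs[0][k], std::max(vs[1][k], vs[2][k]));
    }
  }

  int build(int start, int count, const std::vector<double> &cent) {
    Node nd;
    nd.start = start;
    nd.count = count;
    nd.left = nd.right = -1;
    for (int k = 0; k < 3; ++k) {
      nd.lo[k] = std::numeric_limits<double>::infinity();
      nd.hi[k] = -std::numeric_limits<double>::infinity();
    }
    double tlo[3], thi[3];
    for (int i = start; i < start + count; ++i) {
      tri_bounds(order[i], tlo, thi);
      for (int k = 0; k < 3; ++k) {
        nd.lo[k] = std::min(nd.lo[k], tlo[k]);
        nd.hi[k] = std::max(nd.hi[k], thi[k]);
      }
    }
    int idx = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= 8) return idx;

    // split on longest axis of centroid spread
    double clo[3] = {1e300, 1e300, 1e300}, chi[3] = {-1e300, -1e300, -1e300};
    for (int i = start; i < start + count; ++i) {
      const double *c = &cent[3 * order[i]];
      for (int k = 0; k < 3; ++k) {
        clo[k] = std::min(clo[k], c[k]);
        chi[k] = std::max(chi[k], c[k]);
      }
    }
    int axis = 0;
    double best = chi[0] - clo[0];
    for (int k = 1; k < 3; ++k)
      if (chi[k] - clo[k] > best) { best = chi[k] - clo[k]; axis = k; }
    if (best <= 0.0) return idx;  // all centroids equal: keep as leaf

    int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count,
                     [&](int a, int b) {
                       return cent[3 * a + axis] < cent[3 * b + axis];
                     });
    int l = build(start, mid - start, cent);
    int r = build(mid, start + count - mid, cent);
    nodes[idx].left = l;
    nodes[idx].right = r;
    nodes[idx].count = 0;
    return idx;
  }

  static double box_dist2(const Node &nd, const Vec3 &p) {
    double d2 = 0.0;
    const double pc[3] = {p.x, p.y, p.z};
    for (int k = 0; k < 3; ++k) {
      double d = 0.0;
      if (pc[k] < nd.lo[k]) d = nd.lo[k] - pc[k];
      else if (pc[k] > nd.hi[k]) d = pc[k] - nd.hi[k];
      d2 += d * d;
    }
    return d2;
  }

  void query(int node, const Vec3 &p, double &best2, int &bface, Vec3 &bcp,
             double &bu, double &bv, double &bw) const {
    const Node &nd = nodes[node];
    if (box_dist2(nd, p) >= best2) return;
    if (nd.left < 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        int t = order[i];
        int i0 = F[t], i1 = F[t + m], i2 = F[t + 2 * m];
        Vec3 a = {V[3 * i0], V[3 * i0 + 1], V[3 * i0 + 2]};
        Vec3 b = {V[3 * i1], V[3 * i1 + 1], V[3 * i1 + 2]};
        Vec3 c = {V[3 * i2], V[3 * i2 + 1], V[3 * i2 + 2]};
        double u, v, w;
        Vec3 cp = closest_on_triangle(p, a, b, c, u, v, w);
        Vec3 d = vsub(p, cp);
        double d2 = vdot(d, d);
        if (d2 < best2) {
          best2 = d2; bface = t; bcp = cp; bu = u; bv = v; bw = w;
        }
      }
      return;
    }
    // visit nearer child first for tighter early bounds
    double dl = box_dist2(nodes[nd.left], p);
    double dr = box_dist2(nodes[nd.right], p);
    if (dl <= dr) {
      query(nd.left, p, best2, bface, bcp, bu, bv, bw);
      query(nd.right, p, best2, bface, bcp, bu, bv, bw);
    } else {
      query(nd.right, p, best2, bface, bcp, bu, bv, bw);
      query(nd.left, p, best2, bface, bcp, bu, bv, bw);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".cpp_closest_points")]]
List cpp_closest_points(NumericMatrix V, IntegerMatrix F0, NumericMatrix Q) {
  const int n = V.nrow(), m = F0.nrow(), q = Q.nrow();
  if (m < 1) stop("mesh has no faces");

  // pack vertices row-major
  std::vector<double> vert(3 * n);
  for (int i = 0; i < n; ++i) {
    vert[3 * i] = V(i, 0);
    vert[3 * i + 1] = V(i, 1);
    vert[3 * i + 2] = V(i, 2);
  }
  std::vector<int> fac(3 * m);
  for (int t = 0; t < m; ++t)
    for (int k = 0; k < 3; ++k) {
      int id = F0(t, k);
      if (id < 0 || id >= n) stop("face index out of range");
      fac[t + k * m] = id;
    }

  std::vector<double> cent(3 * m);
  for (int t = 0; t < m; ++t) {
    int i0 = fac[t], i1 = fac[t + m], i2 = fac[t + 2 * m];
    for (int k = 0; k < 3; ++k)
      cent[3 * t + k] =
          (vert[3 * i0 + k] + vert[3 * i1 + k] + vert[3 * i2 + k]) / 3.0;
  }

  BVH bvh;
  bvh.V = vert.data();
  bvh.F = fac.data();
  bvh.m = m;
  bvh.order.resize(m);
  for (int t = 0; t < m; ++t) bvh.order[t] = t;
  bvh.nodes.reserve(2 * m / 8 + 4);
  bvh.build(0, m, cent);

  NumericVector dist(q);
  NumericMatrix cp(q, 3), bary(q, 3);
  IntegerVector face(q);
  for (int i = 0; i < q; ++i) {
    Vec3 p = {Q(i, 0), Q(i, 1), Q(i, 2)};
    double best2 = std::numeric_limits<double>::infinity();
    int bface = -1;
    Vec3 bcp = {0, 0, 0};
    double bu = 0, bv = 0, bw = 0;
    bvh.query(0, p, best2, bface, bcp, bu, bv, bw);
    dist[i] = std::sqrt(best2);
    face[i] = bface + 1;  // back to 1-based for R
    cp(i, 0) = bcp.x; cp(i, 1) = bcp.y; cp(i, 2) = bcp.z;
    bary(i, 0) = bu; bary(i, 1) = bv; bary(i, 2) = bw;
  }
  return List::create(_["distance"] = dist, _["point"] = cp,
                      _["face"] = face, _["bary"] = bary);
}
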