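#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---- small vector helpers -------------------------------------------------

typedef std::array<double, 3> Vec3;

static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  return {a[0] - b[0], a[1] - b[1], a[2] - b[2]};
}
static inline Vec3 vadd(const Vec3 &a, const Vec3 &b) {
  return {a[0] + b[0], a[1] + b[1], a[2] + b[2]};
}
static inline Vec3 vscale(const Vec3 &a, double s) {
  return {a[0] * s, a[1] * s, a[2] * s};
}
static inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double vdist2(const Vec3 &a, const Vec3 &b) {
  Vec3 d = vsub(a, b);
  return vdot(d, d);
}

// Closest point on a closed triangle (a, b, c) to p; Voronoi-region walk.
static Vec3 closest_on_triangle(const Vec3 &p, const Vec3 &a, const Vec3 &b,
                                const Vec3 &c) {
  Vec3 ab = vsub(b, a), ac = vsub(c, a), ap = vsub(p, a);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;

  Vec3 bp = vsub(p, b);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return vadd(a, vscale(ab, v));
  }

  Vec3 cp = vsub(p, c);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return vadd(a, vscale(ac, w));
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return vadd(b, vscale(vsub(c, b), w));
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return vadd(a, vadd(vscale(ab, v), vscale(ac, w)));
}

// [[Rcpp::export]]
List cpp_point_triangle(NumericVector p, NumericMatrix tri) {
  Vec3 pp = {p[0], p[1], p[2]};
  Vec3 a = {tri(0, 0), tri(0, 1), tri(0, 2)};
  Vec3 b = {tri(1, 0), tri(1, 1), tri(1, 2)};
  Vec3 c = {tri(2, 0), tri(2, 1), tri(2, 2)};
  Vec3 q = closest_on_triangle(pp, a, b, c);
  return List::create(_["distance"] = std::sqrt(vdist2(pp, q)),
                      _["closest"] = NumericVector::create(q[0], q[1], q[2]));
}

// ---- BVH over triangle AABBs ---------------------------------------------

struct Box {
  Vec3 lo, hi;
};

static inline double box_dist2(const Box &bx, const Vec3 &p) {
  double d2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = 0.0;
    if (p[k] < bx.lo[k]) d = bx.lo[k] - p[k];
    else if (p[k] > bx.hi[k]) d = p[k] - bx.hi[k];
    d2 += d * d;
  }
  return d2;
}

struct BVHNode {
  Box box;
  int left, right;   // children; -1 for leaf
  int start, count;  // triangle index range for leaves
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order;         // permutation of triangle indices
  std::vector<Vec3> va, vb, vc;   // triangle vertices by original index
  std::vector<Vec3> centroid;
};

static Box tri_box(const BVH &t, int i) {
  Box b;
  for (int k = 0; k < 3; ++k) {
    b.lo[k] = std::min(t.va[i][k], std::min(t.vb[i][k], t.vc[i][k]));
    b.hi[k] = std::max(t.va[i][k], std::max(t.vb[i][k], t.vc[i][k]));
  }
  return b;
}

static int build_node(BVH &t, int start, int count) {
  BVHNode nd;
  nd.start = start;
  nd.count = count;
  nd.left = nd.right = -1;
  Box bx;
  for (int k = 0; k < 3; ++k) {
    bx.lo[k] = std::numeric_limits<double>::infinity();
    bx.hi[k] = -std::numeric_limits<double>::infinity();
  }
  for (int i = start; i < start + count; ++i) {
    Box tb = tri_box(t, t.order[i]);
    for (int k = 0; k < 3; ++k) {
      bx.lo[k] = std::min(bx.lo[k], tb.lo[k]);
      bx.hi[k] = std::max(bx.hi[k], tb.hi[k]);
    }
  }
  nd.box = bx;
  int me = (int)t.nodes.size();
  t.nodes.push_back(nd);
  if (count <= 8) return me;

  int axis = 0;
  double best = bx.hi[0] - bx.lo[0];
  for (int k = 1; k < 3; ++k) {
    double ext = bx.hi[k] - bx.lo[k];
    if (ext > best) { best = ext; axis = k; }
  }
  int mid = start + count / 2;
  std::nth_element(t.order.begin() + start, t.order.begin() + mid,
                   t.order.begin() + start + count, [&](int i, int j) {
                     return t.centroid[i][axis] < t.centroid[j][axis];
                   });
  int l = build_node(t, start, count / 2);
  int r = build_node(t, mid, count - count / 2);
  t.nodes[me].left = l;
  t.nodes[me].right = r;
  return me;
}

static void bvh_query(const BVH &t, const Vec3 &p, double &best2, Vec3 &bestq) {
  // iterative traversal, nearest-child first
  std::vector<int> stack;
  stack.reserve(64);
  stack.push_back(0);
  while (!stack.empty()) {
    int ni = stack.back();
    stack.pop_back();
    const BVHNode &nd = t.nodes[ni];
    if (box_dist2(nd.box, p) >= best2) continue;
    if (nd.left < 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        int ti = t.order[i];
        Vec3 q = closest_on_triangle(p, t.va[ti], t.vb[ti], t.vc[ti]);
        double d2 = vdist2(p, q);
        if (d2 < best2) { best2 = d2; bestq = q; }
      }
    } else {
      double dl = box_dist2(t.nodes[nd.left].box, p);
      double dr = box_dist2(t.nodes[nd.right].box, p);
      // push farther first so nearer is processed first
      if (dl < dr) {
        if (dr < best2) stack.push_back(nd.right);
        if (dl < best2) stack.push_back(nd.left);
      } else {
        if (dl < best2) stack.push_back(nd.left);
        if (dr < best2) stack.push_back(nd.right);
      }
    }
  }
}

// points: n x 3; vertices: m x 3; faces: f x 3 (0-based).
// brute = exhaustive scan over all triangles (reference path).
// [[Rcpp::export]]
List cpp_cloud_mesh(NumericMatrix points, NumericMatrix vertices,
                    IntegerMatrix faces, bool brute, bool return_closest) {
  int n = points.nrow(), nf = faces.nrow();
  BVH t;
  t.va.resize(nf);
  t.vb.resize(nf);
  t.vc.resize(nf);
  t.centroid.resize(nf);
  for (int i = 0; i < nf; ++i) {
    int ia = faces(i, 0), ib = faces(i, 1), ic = faces(i, 2);
    t.va[i] = {vertices(ia, 0), vertices(ia, 1), vertices(ia, 2)};
    t.vb[i] = {vertices(ib, 0), vertices(ib, 1), vertices(ib, 2)};
    t.vc[i] = {vertices(ic, 0), vertices(ic, 1), vertices(ic, 2)};
    for (int k = 0; k < 3; ++k)
      t.centroid[i][k] = (t.va[i][k] + t.vb[i][k] + t.vc[i][k]) / 3.0;
  }

  NumericVector dist(n);
  NumericMatrix closest(return_closest ? n : 1, 3);

  if (brute) {
    for (int j = 0; j < n; ++j) {
      Vec3 p = {points(j, 0), points(j, 1), points(j, 2)};
      double best2 = std::numeric_limits<double>::infinity();
      Vec3 bq = {0, 0, 0};
      for (int i = 0; i < nf; ++i) {
        Vec3 q = closest_on_triangle(p, t.va[i], t.vb[i], t.vc[i]);
        double d2 = vdist2(p, q);
        if (d2 < best2) { best2 = d2; bq = q; }
      }
      dist[j] = std::sqrt(best2);
      if (return_closest)
        for (int k = 0; k < 3; ++k) closest(j, k) = bq[k];
    }
  } else {
    t.order.resize(nf);
    for (int i = 0; i < nf; ++i) t.order[i] = i;
    build_node(t, 0, nf);
    for (int j = 0; j < n; ++j) {
      Vec3 p = {points(j, 0), points(j, 1), points(j, 2)};
      double best2 = std::numeric_limits<double>::infinity();
      Vec3 bq = {0, 0, 0};
      bvh_query(t, p, best2, bq);
      dist[j] = std::sqrt(best2);
      if (return_closest)
        for (int k = 0; k < 3; ++k) closest(j, k) = bq[k];
    }
  }

  if (return_closest)
    return List::create(_["distance"] = dist, _["closest"] = closest);
  return List::create(_["distance"] = dist);
}
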