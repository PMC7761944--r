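// Exact closest-point queries from points to a triangle mesh.
// A static median-split BVH over triangle bounding boxes gives O(log m)
// queries; the point-triangle distance is Ericson's region test, so face
// interiors, edges and vertices are all candidate features (exact nearest
// neighbour search, not vertex-to-vertex).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
};

// Closest point on triangle abc to p; bary receives barycentric coords (u,v,w)
// with closest = u*a + v*b + w*c.
Vec3 closestPointTriangle(const Vec3& p, const Vec3& a, const Vec3& b,
                          const Vec3& c, double* bary) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = ab.dot(ap), d2 = ac.dot(ap);
  if (d1 <= 0.0 && d2 <= 0.0) {
    bary[0] = 1; bary[1] = 0; bary[2] = 0;
    return a;
  }
  Vec3 bp = p - b;
  double d3 = ab.dot(bp), d4 = ac.dot(bp);
  if (d3 >= 0.0 && d4 <= d3) {
    bary[0] = 0; bary[1] = 1; bary[2] = 0;
    return b;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = (d1 - d3 != 0.0) ? d1 / (d1 - d3) : 0.0;
    bary[0] = 1 - v; bary[1] = v; bary[2] = 0;
    return a + ab * v;
  }
  Vec3 cp = p - c;
  double d5 = ab.dot(cp), d6 = ac.dot(cp);
  if (d6 >= 0.0 && d5 <= d6) {
    bary[0] = 0; bary[1] = 0; bary[2] = 1;
    return c;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = (d2 - d6 != 0.0) ? d2 / (d2 - d6) : 0.0;
    bary[0] = 1 - w; bary[1] = 0; bary[2] = w;
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double denom = (d4 - d3) + (d5 - d6);
    double w = (denom != 0.0) ? (d4 - d3) / denom : 0.0;
    bary[0] = 0; bary[1] = 1 - w; bary[2] = w;
    return b + (c - b) * w;
  }
  double denom = va + vb + vc;
  double v = vb / denom, w = vc / denom;
  bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
  return a + ab * v + ac * w;
}

struct BVHNode {
  double lo[3], hi[3];
  int left, right;   // children, or -1 for leaf
  int begin, end;    // triangle index range (into order) for leaves
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order;
  const double* V; const int* F;
  int nv, nf;

  double boxDist2(const BVHNode& n, const Vec3& p) const {
    double d2 = 0.0;
    double c[3] = {p.x, p.y, p.z};
    for (int k = 0; k < 3; ++k) {
      double d = 0.0;
      if (c[k] < n.lo[k]) d = n.lo[k] - c[k];
      else if (c[k] > n.hi[k]) d = c[k] - n.hi[k];
      d2 += d * d;
    }
    return d2;
  }

  Vec3 vert(int i) const { return Vec3(V[i], V[nv + i], V[2 * nv + i]); }

  int build(int begin, int end, std::vector<Vec3>& cent) {
    BVHNode node;
    node.lo[0] = node.lo[1] = node.lo[2] = std::numeric_limits<double>::infinity();
    node.hi[0] = node.hi[1] = node.hi[2] = -std::numeric_limits<double>::infinity();
    for (int t = begin; t < end; ++t) {
      int f = order[t];
      for (int j = 0; j < 3; ++j) {
        Vec3 v = vert(F[j * nf + f] - 1);
        double c[3] = {v.x, v.y, v.z};
        for (int k = 0; k < 3; ++k) {
          node.lo[k] = std::min(node.lo[k], c[k]);
          node.hi[k] = std::max(node.hi[k], c[k]);
        }
      }
    }
    node.begin = begin; node.end = end;
    if (end - begin <= 8) {
      node.left = node.right = -1;
      nodes.push_back(node);
      return (int)nodes.size() - 1;
    }
    // split on longest axis of centroid spread
    double clo[3] = {1e300, 1e300, 1e300}, chi[3] = {-1e300, -1e300, -1e300};
    for (int t = begin; t < end; ++t) {
      const Vec3& c = cent[order[t]];
      double a[3] = {c.x, c.y, c.z};
      for (int k = 0; k < 3; ++k) {
        clo[k] = std::min(clo[k], a[k]);
        chi[k] = std::max(chi[k], a[k]);
      }
    }
    int axis = 0;
    double best = chi[0] - clo[0];
    for (int k = 1; k < 3; ++k)
      if (chi[k] - clo[k] > best) { best = chi[k] - clo[k]; axis = k; }
    int mid = (begin + end) / 2;
    std::nth_element(order.begin() + begin, order.begin() + mid,
                     order.begin() + end, [&](int a, int b) {
                       double ca = axis == 0 ? cent[a].x : (axis == 1 ? cent[a].y : cent[a].z);
                       double cb = axis == 0 ? cent[b].x : (axis == 1 ? cent[b].y : cent[b].z);
                       return ca < cb;
                     });
    int self = (int)nodes.size();
    nodes.push_back(node);  // placeholder; fix children after recursion
    int l = build(begin, mid, cent);
    int r = build(mid, end, cent);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }

  void query(const Vec3& p, double& bestD2, Vec3& bestPt, int& bestFace,
             double* bestBary, int nodeIdx) const {
    const BVHNode& n = nodes[nodeIdx];
    if (boxDist2(n, p) >= bestD2) return;
    if (n.left < 0) {
      for (int t = n.begin; t < n.end; ++t) {
        int f = order[t];
        Vec3 a = vert(F[f] - 1), b = vert(F[nf + f] - 1), c = vert(F[2 * nf + f] - 1);
        double bary[3];
        Vec3 q = closestPointTriangle(p, a, b, c, bary);
        Vec3 d = p - q;
        double d2 = d.dot(d);
        if (d2 < bestD2) {
          bestD2 = d2; bestPt = q; bestFace = f;
          bestBary[0] = bary[0]; bestBary[1] = bary[1]; bestBary[2] = bary[2];
        }
      }
      return;
    }
    double dl = boxDist2(nodes[n.left], p), dr = boxDist2(nodes[n.right], p);
    if (dl < dr) {
      query(p, bestD2, bestPt, bestFace, bestBary, n.left);
      query(p, bestD2, bestPt, bestFace, bestBary, n.right);
    } else {
      query(p, bestD2, bestPt, bestFace, bestBary, n.right);
      query(p, bestD2, bestPt, bestFace, bestBary, n.left);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".cppClosestPoints")]]
NumericMatrix cppClosestPoints(NumericMatrix points, NumericMatrix vertices,
                               IntegerMatrix faces) {
  int np = points.nrow(), nf = faces.nrow(), nv = vertices.nrow();
  if (nf < 1) stop("target mesh has no faces");
  BVH bvh;
  bvh.V = vertices.begin();
  bvh.F = faces.begin();
  bvh.nv = nv;
  bvh.nf = nf;
  bvh.order.resize(nf);
  for (int i = 0; i < nf; ++i) bvh.order[i] = i;
  std::vector<Vec3> cent(nf);
  for (int f = 0; f < nf; ++f) {
    Vec3 a = bvh.vert(faces(f, 0) - 1), b = bvh.vert(faces(f, 1) - 1),
         c = bvh.vert(faces(f, 2) - 1);
    cent[f] = (a + b + c) * (1.0 / 3.0);
  }
  int root = bvh.build(0, nf, cent);

  NumericMatrix out(np, 8);  // cx cy cz dist face b0 b1 b2
  for (int i = 0; i < np; ++i) {
    Vec3 p(points(i, 0), points(i, 1), points(i, 2));
    double bestD2 = std::numeric_limits<double>::infinity();
    Vec3 bestPt;
    int bestFace = -1;
    double bary[3] = {0, 0, 0};
    bvh.query(p, bestD2, bestPt, bestFace, bary, root);
    out(i, 0) = bestPt.x;
    out(i, 1) = bestPt.y;
    out(i, 2) = bestPt.z;
    out(i, 3) = std::sqrt(bestD2);
    out(i, 4) = bestFace + 1;
    out(i, 5) = bary[0];
    out(i, 6) = bary[1];
    out(i, 7) = bary[2];
  }
  return out;
}
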