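// Compiled geometry kernels for 3D mask morphometrics:
//  - incremental quickhull over voxel centers (full-rank point sets only;
//    degenerate ranks are handled on the R side),
//  - counting lattice points inside the hull's half-space intersection,
//  - isosurface area by marching tetrahedra on a padded, optionally
//    Gaussian-smoothed copy of the binary grid.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <utility>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3& a, const Vec3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Facet {
  int v[3];
  Vec3 n;       // outward normal (not normalized)
  double d;     // plane offset: inside means dot(n, p) <= d
  int nb[3];    // neighbor across edge (v[i], v[(i+1)%3])
  std::vector<int> out;
  bool alive;
};

inline double fdist(const Facet& f, const Vec3& p) { return dot(f.n, p) - f.d; }

class Hull {
public:
  std::vector<Vec3> pts;
  std::vector<Facet> facets;
  double eps;

  explicit Hull(const NumericMatrix& P) {
    int n = P.nrow();
    pts.resize(n);
    double scale = 1.0;
    for (int i = 0; i < n; ++i) {
      pts[i] = {P(i, 0), P(i, 1), P(i, 2)};
      scale = std::max(scale, std::fabs(pts[i].x));
      scale = std::max(scale, std::fabs(pts[i].y));
      scale = std::max(scale, std::fabs(pts[i].z));
    }
    eps = 1e-9 * scale * 3.0;
  }

  void buildInitialSimplex(int s[4]) {
    int n = (int)pts.size();
    // extremes along coordinate axes
    int ext[6] = {0, 0, 0, 0, 0, 0};
    for (int i = 1; i < n; ++i) {
      if (pts[i].x < pts[ext[0]].x) ext[0] = i;
      if (pts[i].x > pts[ext[1]].x) ext[1] = i;
      if (pts[i].y < pts[ext[2]].y) ext[2] = i;
      if (pts[i].y > pts[ext[3]].y) ext[3] = i;
      if (pts[i].z < pts[ext[4]].z) ext[4] = i;
      if (pts[i].z > pts[ext[5]].z) ext[5] = i;
    }
    double best = -1.0;
    for (int a = 0; a < 6; ++a)
      for (int b = a + 1; b < 6; ++b) {
        double d = norm(sub(pts[ext[a]], pts[ext[b]]));
        if (d > best) { best = d; s[0] = ext[a]; s[1] = ext[b]; }
      }
    if (best <= eps) stop("degenerate point set (rank 0) passed to quickhull");
    // farthest from the line s0-s1
    Vec3 dir = sub(pts[s[1]], pts[s[0]]);
    best = -1.0; s[2] = -1;
    for (int i = 0; i < n; ++i) {
      double d = norm(cross(dir, sub(pts[i], pts[s[0]])));
      if (d > best) { best = d; s[2] = i; }
    }
    if (best / std::max(norm(dir), 1.0) <= eps)
      stop("degenerate point set (rank 1) passed to quickhull");
    // farthest from the plane s0-s1-s2
    Vec3 nrm = cross(sub(pts[s[1]], pts[s[0]]), sub(pts[s[2]], pts[s[0]]));
    double nn = norm(nrm);
    best = -1.0; s[3] = -1;
    double bestSigned = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = dot(nrm, sub(pts[i], pts[s[0]])) / nn;
      if (std::fabs(d) > best) { best = std::fabs(d); s[3] = i; bestSigned = d; }
    }
    if (best <= eps) stop("degenerate point set (rank 2) passed to quickhull");
    if (bestSigned > 0) std::swap(s[1], s[2]);  // make tetra orientation canonical
  }

  int addFacet(int a, int b, int c, const Vec3& interior) {
    Facet f;
    f.v[0] = a; f.v[1] = b; f.v[2] = c;
    f.n = cross(sub(pts[b], pts[a]), sub(pts[c], pts[a]));
    f.d = dot(f.n, pts[a]);
    if (dot(f.n, interior) - f.d > 0) {  // flip to outward
      std::swap(f.v[1], f.v[2]);
      f.n = {-f.n.x, -f.n.y, -f.n.z};
      f.d = -f.d;
    }
    f.nb[0] = f.nb[1] = f.nb[2] = -1;
    f.alive = true;
    facets.push_back(f);
    return (int)facets.size() - 1;
  }

  // epsilon scaled by normal length, since normals are not unit
  inline bool visible(const Facet& f, const Vec3& p) const {
    return fdist(f, p) > eps * std::max(1.0, norm(f.n));
  }

  void linkNeighbors(const std::vector<int>& ids) {
    std::map<std::pair<int, int>, std::pair<int, int>> edges;  // edge -> (facet, slot)
    for (int id : ids) {
      Facet& f = facets[id];
      for (int e = 0; e < 3; ++e) {
        int a = f.v[e], b = f.v[(e + 1) % 3];
        auto key = std::make_pair(std::min(a, b), std::max(a, b));
        auto it = edges.find(key);
        if (it == edges.end()) {
          edges[key] = {id, e};
        } else {
          f.nb[e] = it->second.first;
          facets[it->second.first].nb[it->second.second] = id;
          edges.erase(it);
        }
      }
    }
  }

  void build() {
    int n = (int)pts.size();
    int s[4];
    buildInitialSimplex(s);
    Vec3 interior = {
      (pts[s[0]].x + pts[s[1]].x + pts[s[2]].x + pts[s[3]].x) / 4.0,
      (pts[s[0]].y + pts[s[1]].y + pts[s[2]].y + pts[s[3]].y) / 4.0,
      (pts[s[0]].z + pts[s[1]].z + pts[s[2]].z + pts[s[3]].z) / 4.0};
    std::vector<int> ids;
    ids.push_back(addFacet(s[0], s[1], s[2], interior));
    ids.push_back(addFacet(s[0], s[1], s[3], interior));
    ids.push_back(addFacet(s[0], s[2], s[3], interior));
    ids.push_back(addFacet(s[1], s[2], s[3], interior));
    linkNeighbors(ids);

    // initial conflict assignment: farthest-visible facet wins the point
    for (int i = 0; i < n; ++i) {
      if (i == s[0] || i == s[1] || i == s[2] || i == s[3]) continue;
      int bestF = -1; double bestD = 0.0;
      for (int id : ids) {
        double d = fdist(facets[id], pts[i]) / std::max(1.0, norm(facets[id].n));
        if (d > eps && d > bestD) { bestD = d; bestF = id; }
      }
      if (bestF >= 0) facets[bestF].out.push_back(i);
    }

    std::vector<int> stack;
    for (int id : ids) if (!facets[id].out.empty()) stack.push_back(id);

    std::vector<int> visibleSet, orphans;
    while (!stack.empty()) {
      int fid = stack.back(); stack.pop_back();
      if (!facets[fid].alive || facets[fid].out.empty()) continue;
      // farthest outside point of this facet
      int p = -1; double bestD = -1.0;
      double nl = std::max(1.0, norm(facets[fid].n));
      for (int i : facets[fid].out) {
        double d = fdist(facets[fid], pts[i]) / nl;
        if (d > bestD) { bestD = d; p = i; }
      }
      const Vec3& ap = pts[p];

      // BFS for all facets visible from p
      visibleSet.clear();
      std::vector<int> q;
      q.push_back(fid);
      std::vector<char> seen(facets.size(), 0);
      seen[fid] = 1;
      while (!q.empty()) {
        int g = q.back(); q.pop_back();
        if (!facets[g].alive || !visible(facets[g], ap)) continue;
        visibleSet.push_back(g);
        for (int e = 0; e < 3; ++e) {
          int nbid = facets[g].nb[e];
          if (nbid >= 0 && !seen[nbid]) { seen[nbid] = 1; q.push_back(nbid); }
        }
      }
      if (visibleSet.empty()) continue;
      std::vector<char> isVis(facets.size(), 0);
      for (int g : visibleSet) isVis[g] = 1;

      // horizon edges (oriented as in the visible facet), orphaned points
      std::vector<std::pair<std::pair<int, int>, int>> horizon;  // (edge a->b, outside neighbor)
      orphans.clear();
      for (int g : visibleSet) {
        Facet& f = facets[g];
        for (int e = 0; e < 3; ++e) {
          int nbid = f.nb[e];
          if (nbid < 0 || !isVis[nbid])
            horizon.push_back({{f.v[e], f.v[(e + 1) % 3]}, nbid});
        }
        for (int i : f.out) if (i != p) orphans.push_back(i);
      }
      for (int g : visibleSet) {  // kill only after horizon collection
        facets[g].alive = false;
        facets[g].out.clear();
      }

      // cone of new facets from p over the horizon
      std::map<std::pair<int, int>, std::pair<int, int>> open;  // edge -> (facet, slot)
      std::vector<int> newIds;
      for (auto& h : horizon) {
        int a = h.first.first, b = h.first.second, outsideNb = h.second;
        int id = addFacet(a, b, p, interior);
        Facet& f = facets[id];
        // locate each edge slot by vertex content (orientation may have flipped)
        for (int e = 0; e < 3; ++e) {
          int u = f.v[e], w = f.v[(e + 1) % 3];
          if ((u == a && w == b) || (u == b && w == a)) {
            f.nb[e] = outsideNb;
            if (outsideNb >= 0) {
              Facet& g = facets[outsideNb];
              for (int e2 = 0; e2 < 3; ++e2) {
                int u2 = g.v[e2], w2 = g.v[(e2 + 1) % 3];
                if ((u2 == a && w2 == b) || (u2 == b && w2 == a)) g.nb[e2] = id;
              }
            }
          } else {
            auto key = std::make_pair(std::min(u, w), std::max(u, w));
            auto it = open.find(key);
            if (it == open.end()) {
              open[key] = {id, e};
            } else {
              f.nb[e] = it->second.first;
              facets[it->second.first].nb[it->second.second] = id;
              open.erase(it);
            }
          }
        }
        newIds.push_back(id);
      }

      // reassign orphans to their farthest-visible new facet
      for (int i : orphans) {
        int bestF = -1; double bd = 0.0;
        for (int id : newIds) {
          double d = fdist(facets[id], pts[i]) / std::max(1.0, norm(facets[id].n));
          if (d > eps && d > bd) { bd = d; bestF = id; }
        }
        if (bestF >= 0) facets[bestF].out.push_back(i);
      }
      for (int id : newIds) if (!facets[id].out.empty()) stack.push_back(id);
    }
  }
};

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_hull_planes")]]
NumericMatrix cpp_hull_planes(NumericMatrix pts) {
  Hull h(pts);
  h.build();
  int m = 0;
  for (const auto& f : h.facets) if (f.alive) ++m;
  NumericMatrix planes(m, 4);  // unit normal (a,b,c) and offset d; inside: ax+by+cz <= d
  int r = 0;
  for (const auto& f : h.facets) {
    if (!f.alive) continue;
    double nl = norm(f.n);
    planes(r, 0) = f.n.x / nl;
    planes(r, 1) = f.n.y / nl;
    planes(r, 2) = f.n.z / nl;
    planes(r, 3) = f.d / nl;
    ++r;
  }
  return planes;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_count_lattice_in_halfspaces")]]
double cpp_count_lattice_in_halfspaces(NumericMatrix planes, IntegerVector lo,
                                       IntegerVector hi, double tol) {
  int m = planes.nrow();
  std::vector<double> a(m), b(m), c(m), d(m);
  for (int i = 0; i < m; ++i) {
    a[i] = planes(i, 0); b[i] = planes(i, 1); c[i] = planes(i, 2);
    d[i] = planes(i, 3) + tol;
  }
  double count = 0;
  for (int x = lo[0]; x <= hi[0]; ++x)
    for (int y = lo[1]; y <= hi[1]; ++y) {
      // precompute the x,y part once per column
      for (int z = lo[2]; z <= hi[2]; ++z) {
        bool inside = true;
        for (int i = 0; i < m; ++i) {
          if (a[i] * x + b[i] * y + c[i] * z > d[i]) { inside = false; break; }
        }
        if (inside) count += 1;
      }
    }
  return count;
}

namespace {

inline double triArea(const Vec3& a, const Vec3& b, const Vec3& c) {
  return 0.5 * norm(cross(sub(b, a), sub(c, a)));
}

// separable truncated-Gaussian smoothing along one axis, in place via buffer
void smoothAxis(std::vector<double>& v, int nx, int ny, int nz, int axis,
                const std::vector<double>& k) {
  int R = (int)(k.size() - 1) / 2;
  std::vector<double> out(v.size());
  auto idx = [&](int x, int y, int z) { return (std::int64_t)x + (std::int64_t)nx * (y + (std::int64_t)ny * z); };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double s = 0.0;
        for (int t = -R; t <= R; ++t) {
          int xx = x, yy = y, zz = z;
          if (axis == 0) xx += t; else if (axis == 1) yy += t; else zz += t;
          double val = 0.0;  // zero padding outside
          if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
            val = v[idx(xx, yy, zz)];
          s += k[t + R] * val;
        }
        out[idx(x, y, z)] = s;
      }
  v.swap(out);
}

double mtArea(const std::vector<double>& v, int nx, int ny, int nz,
              double sx, double sy, double sz, double level) {
  auto idx = [&](int x, int y, int z) { return (std::int64_t)x + (std::int64_t)nx * (y + (std::int64_t)ny * z); };
  // cube corner offsets; the six tetrahedra share the 0-6 diagonal
  static const int off[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};
  double area = 0.0;
  Vec3 corner[8];
  double val[8];
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        bool anyPos = false, anyNeg = false;
        for (int c = 0; c < 8; ++c) {
          val[c] = v[idx(x + off[c][0], y + off[c][1], z + off[c][2])] - level;
          (val[c] > 0 ? anyPos : anyNeg) = true;
          corner[c] = {(x + off[c][0]) * sx, (y + off[c][1]) * sy, (z + off[c][2]) * sz};
        }
        if (!anyPos || !anyNeg) continue;
        for (int t = 0; t < 6; ++t) {
          int pos[4], neg[4], np = 0, nn = 0;
          for (int j = 0; j < 4; ++j) {
            int c = tets[t][j];
            if (val[c] > 0) pos[np++] = c; else neg[nn++] = c;
          }
          if (np == 0 || np == 4) continue;
          auto edgePt = [&](int p, int q) {
            double tfrac = val[p] / (val[p] - val[q]);
            return Vec3{corner[p].x + tfrac * (corner[q].x - corner[p].x),
                        corner[p].y + tfrac * (corner[q].y - corner[p].y),
                        corner[p].z + tfrac * (corner[q].z - corner[p].z)};
          };
          if (np == 1) {
            area += triArea(edgePt(pos[0], neg[0]), edgePt(pos[0], neg[1]), edgePt(pos[0], neg[2]));
          } else if (np == 3) {
            area += triArea(edgePt(pos[0], neg[0]), edgePt(pos[1], neg[0]), edgePt(pos[2], neg[0]));
          } else {  // np == 2: quad split into two triangles
            Vec3 q1 = edgePt(pos[0], neg[0]), q2 = edgePt(pos[0], neg[1]);
            Vec3 q3 = edgePt(pos[1], neg[1]), q4 = edgePt(pos[1], neg[0]);
            area += triArea(q1, q2, q3) + triArea(q1, q3, q4);
          }
        }
      }
  return area;
}

}  // namespace

namespace {

// trilinear refinement by integer factor u: output node k maps to input
// coordinate k / u
std::vector<double> upsample(const std::vector<double>& v, int nx, int ny, int nz,
                             int u, int& ox, int& oy, int& oz) {
  ox = (nx - 1) * u + 1; oy = (ny - 1) * u + 1; oz = (nz - 1) * u + 1;
  std::vector<double> out((std::int64_t)ox * oy * oz);
  auto idx = [&](int x, int y, int z) { return (std::int64_t)x + (std::int64_t)nx * (y + (std::int64_t)ny * z); };
  auto odx = [&](int x, int y, int z) { return (std::int64_t)x + (std::int64_t)ox * (y + (std::int64_t)oy * z); };
  for (int z = 0; z < oz; ++z) {
    double fz = (double)z / u;
    int z0 = std::min((int)fz, nz - 2); double tz = fz - z0;
    for (int y = 0; y < oy; ++y) {
      double fy = (double)y / u;
      int y0 = std::min((int)fy, ny - 2); double ty = fy - y0;
      for (int x = 0; x < ox; ++x) {
        double fx = (double)x / u;
        int x0 = std::min((int)fx, nx - 2); double tx = fx - x0;
        double c00 = v[idx(x0, y0, z0)] * (1 - tx) + v[idx(x0 + 1, y0, z0)] * tx;
        double c10 = v[idx(x0, y0 + 1, z0)] * (1 - tx) + v[idx(x0 + 1, y0 + 1, z0)] * tx;
        double c01 = v[idx(x0, y0, z0 + 1)] * (1 - tx) + v[idx(x0 + 1, y0, z0 + 1)] * tx;
        double c11 = v[idx(x0, y0 + 1, z0 + 1)] * (1 - tx) + v[idx(x0 + 1, y0 + 1, z0 + 1)] * tx;
        out[odx(x, y, z)] = (c00 * (1 - ty) + c10 * ty) * (1 - tz) +
                            (c01 * (1 - ty) + c11 * ty) * tz;
      }
    }
  }
  return out;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_isosurface_area")]]
double cpp_isosurface_area(NumericVector grid, IntegerVector dim, NumericVector spacing,
                           double sigma, double level, int refine) {
  int gx = dim[0], gy = dim[1], gz = dim[2];
  int R = sigma > 0 ? std::max(1, (int)std::ceil(3.0 * sigma)) : 0;
  int pad = R + 2;
  int nx = gx + 2 * pad, ny = gy + 2 * pad, nz = gz + 2 * pad;
  std::vector<double> v((std::int64_t)nx * ny * nz, 0.0);
  auto idx = [&](int x, int y, int z) { return (std::int64_t)x + (std::int64_t)nx * (y + (std::int64_t)ny * z); };
  for (int z = 0; z < gz; ++z)
    for (int y = 0; y < gy; ++y)
      for (int x = 0; x < gx; ++x)
        v[idx(x + pad, y + pad, z + pad)] =
            grid[(std::int64_t)x + (std::int64_t)gx * (y + (std::int64_t)gy * z)];
  std::vector<double> raw;
  if (sigma > 0) {
    raw = v;
    std::vector<double> k(2 * R + 1);
    double s = 0.0;
    for (int t = -R; t <= R; ++t) { k[t + R] = std::exp(-0.5 * t * t / (sigma * sigma)); s += k[t + R]; }
    for (auto& w : k) w /= s;
    smoothAxis(v, nx, ny, nz, 0, k);
    smoothAxis(v, nx, ny, nz, 1, k);
    smoothAxis(v, nx, ny, nz, 2, k);
    double mx = 0.0;
    for (double w : v) mx = std::max(mx, w);
    if (mx <= level) v.swap(raw);  // region too small for the smoothed field: use the raw grid
  }
  if (refine > 1) {
    int ox, oy, oz;
    std::vector<double> vu = upsample(v, nx, ny, nz, refine, ox, oy, oz);
    return mtArea(vu, ox, oy, oz, spacing[0] / refine, spacing[1] / refine,
                  spacing[2] / refine, level);
  }
  return mtArea(v, nx, ny, nz, spacing[0], spacing[1], spacing[2], level);
}

// Coordinate-descent LASSO path solver (gaussian objective
// (1/(2n))||y - b0 - X b||^2 + lambda ||b||_1). Columns are centered
// internally so the unpenalized intercept is handled exactly; covariance
// updates make each sweep O(p^2). Warm starts along the decreasing lambda
// grid give exact zeros at and above lambda_max.
//' @noRd
// [[Rcpp::export(name = ".cpp_lasso_path")]]
List cpp_lasso_path(NumericMatrix X, NumericVector y, NumericVector lambda,
                    double tol, int maxit) {
  int n = X.nrow(), p = X.ncol(), L = lambda.size();
  std::vector<double> xm(p), d(p);
  double ym = 0.0;
  for (int i = 0; i < n; ++i) ym += y[i];
  ym /= n;
  std::vector<double> Xc((std::int64_t)n * p), yc(n);
  for (int i = 0; i < n; ++i) yc[i] = y[i] - ym;
  for (int j = 0; j < p; ++j) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += X(i, j);
    xm[j] = m / n;
    for (int i = 0; i < n; ++i) Xc[(std::int64_t)j * n + i] = X(i, j) - xm[j];
  }
  // gram = X'X / n, xty = X'y / n (centered)
  std::vector<double> gram((std::int64_t)p * p), xty(p);
  for (int j = 0; j < p; ++j) {
    const double* xj = &Xc[(std::int64_t)j * n];
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * yc[i];
    xty[j] = s / n;
    for (int k = 0; k <= j; ++k) {
      const double* xk = &Xc[(std::int64_t)k * n];
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += xj[i] * xk[i];
      gram[(std::int64_t)j * p + k] = gram[(std::int64_t)k * p + j] = g / n;
    }
    d[j] = gram[(std::int64_t)j * p + j];
  }
  // convergence measured like the usual coordinate-descent packages: the
  // largest per-update squared objective change d_j * (delta beta_j)^2,
  // relative to the outcome variance
  double vy = 0.0;
  for (int i = 0; i < n; ++i) vy += yc[i] * yc[i];
  vy = std::max(vy / n, 1e-300);
  NumericMatrix beta(p, L);
  NumericVector b0(L);
  std::vector<double> b(p, 0.0), gb(p, 0.0);  // gb = gram %*% b
  for (int l = 0; l < L; ++l) {
    double lam = lambda[l];
    for (int it = 0; it < maxit; ++it) {
      double maxdel = 0.0;
      for (int j = 0; j < p; ++j) {
        if (d[j] < 1e-12) { b[j] = 0.0; continue; }
        double rho = xty[j] - gb[j] + d[j] * b[j];
        // tiny relative slack so a lambda_max computed externally (possibly
        // with a different summation order) still yields exact zeros
        double thr = lam * (1 + 1e-12);
        double bj = 0.0;
        if (rho > thr) bj = (rho - lam) / d[j];
        else if (rho < -thr) bj = (rho + lam) / d[j];
        double del = bj - b[j];
        if (del != 0.0) {
          const double* gj = &gram[(std::int64_t)j * p];
          for (int k = 0; k < p; ++k) gb[k] += gj[k] * del;
          b[j] = bj;
          double sc = d[j] * del * del;
          if (sc > maxdel) maxdel = sc;
        }
      }
      if (maxdel < tol * vy) break;
    }
    double icpt = ym;
    for (int j = 0; j < p; ++j) {
      beta(j, l) = b[j];
      icpt -= b[j] * xm[j];
    }
    b0[l] = icpt;
  }
  return List::create(Named("beta") = beta, Named("a0") = b0,
                      Named("lambda") = lambda);
}
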