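// Incremental Bowyer-Watson Delaunay tetrahedralization.
// Built because no 3D Delaunay is available in the installed R stack; the
// alpha-shape machinery needs the full tetrahedral complex with circumradii.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

namespace {

struct Tet {
  int v[4];      // vertex indices
  int nb[4];     // nb[i] = tet sharing the face opposite v[i]; -1 = outside
  double cx, cy, cz, r2;  // circumsphere (on the jittered working coords)
  bool alive;
};

// splitmix64: deterministic per-coordinate jitter to break cospherical ties
// (voxel-grid inputs are heavily degenerate otherwise).
inline double jitter_hash(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  x = x ^ (x >> 31);
  // map to [-0.5, 0.5)
  return (double)(x >> 11) / 9007199254740992.0 - 0.5;
}

inline double det3(double a, double b, double c,
                   double d, double e, double f,
                   double g, double h, double i) {
  return a * (e * i - f * h) - b * (d * i - f * g) + c * (d * h - e * g);
}

// circumsphere of 4 points; returns false if (near-)degenerate
bool circumsphere(const std::vector<double>& px, const std::vector<double>& py,
                  const std::vector<double>& pz, const int* v,
                  double& cx, double& cy, double& cz, double& r2) {
  const double ax = px[v[0]], ay = py[v[0]], az = pz[v[0]];
  double bx = px[v[1]] - ax, by = py[v[1]] - ay, bz = pz[v[1]] - az;
  double dx = px[v[2]] - ax, dy = py[v[2]] - ay, dz = pz[v[2]] - az;
  double ex = px[v[3]] - ax, ey = py[v[3]] - ay, ez = pz[v[3]] - az;
  double det = det3(bx, by, bz, dx, dy, dz, ex, ey, ez);
  if (std::fabs(det) < 1e-300) return false;
  double b2 = bx * bx + by * by + bz * bz;
  double d2 = dx * dx + dy * dy + dz * dz;
  double e2 = ex * ex + ey * ey + ez * ez;
  double ux = det3(b2, by, bz, d2, dy, dz, e2, ey, ez) / (2.0 * det);
  double uy = det3(bx, b2, bz, dx, d2, dz, ex, e2, ez) / (2.0 * det);
  double uz = det3(bx, by, b2, dx, dy, d2, ex, ey, e2) / (2.0 * det);
  cx = ax + ux; cy = ay + uy; cz = az + uz;
  r2 = ux * ux + uy * uy + uz * uz;
  return true;
}

inline double orient3d(const std::vector<double>& px, const std::vector<double>& py,
                       const std::vector<double>& pz, int a, int b, int c, int d) {
  return det3(px[b] - px[a], py[b] - py[a], pz[b] - pz[a],
              px[c] - px[a], py[c] - py[a], pz[c] - pz[a],
              px[d] - px[a], py[d] - py[a], pz[d] - pz[a]);
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix delaunay3d_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");

  // working coordinates: scaled to the unit box + deterministic jitter
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      double v = pts(i, k);
      if (v < lo[k]) lo[k] = v;
      if (v > hi[k]) hi[k] = v;
    }
  double scale = 0.0;
  for (int k = 0; k < 3; ++k) scale = std::max(scale, hi[k] - lo[k]);
  if (scale <= 0) stop("degenerate point cloud (zero extent)");

  std::vector<double> px(n + 4), py(n + 4), pz(n + 4);
  const double jit = 1e-11;
  for (int i = 0; i < n; ++i) {
    px[i] = (pts(i, 0) - lo[0]) / scale + jit * jitter_hash(3 * (uint64_t)i + 0);
    py[i] = (pts(i, 1) - lo[1]) / scale + jit * jitter_hash(3 * (uint64_t)i + 1);
    pz[i] = (pts(i, 2) - lo[2]) / scale + jit * jitter_hash(3 * (uint64_t)i + 2);
  }
  // super-tetrahedron enclosing the unit box generously
  px[n] = -100; py[n] = -100; pz[n] = -100;
  px[n + 1] = 300; py[n + 1] = -100; pz[n + 1] = -100;
  px[n + 2] = -100; py[n + 2] = 300; pz[n + 2] = -100;
  px[n + 3] = -100; py[n + 3] = -100; pz[n + 3] = 300;

  std::vector<Tet> tets;
  tets.reserve(12 * n);
  {
    Tet t0;
    t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2; t0.v[3] = n + 3;
    if (orient3d(px, py, pz, t0.v[0], t0.v[1], t0.v[2], t0.v[3]) < 0)
      std::swap(t0.v[0], t0.v[1]);
    t0.nb[0] = t0.nb[1] = t0.nb[2] = t0.nb[3] = -1;
    circumsphere(px, py, pz, t0.v, t0.cx, t0.cy, t0.cz, t0.r2);
    t0.alive = true;
    tets.push_back(t0);
  }

  std::vector<int> bad, stack;
  std::vector<char> is_bad;
  for (int ip = 0; ip < n; ++ip) {
    const double qx = px[ip], qy = py[ip], qz = pz[ip];
    // seed: any alive tet whose circumsphere contains the point
    int seed = -1;
    for (int t = (int)tets.size() - 1; t >= 0; --t) {
      if (!tets[t].alive) continue;
      double dx = qx - tets[t].cx, dy = qy - tets[t].cy, dz = qz - tets[t].cz;
      if (dx * dx + dy * dy + dz * dz < tets[t].r2) { seed = t; break; }
    }
    if (seed < 0) stop("point outside all circumspheres (numerical failure)");

    // BFS over face-adjacency collecting the connected bad region
    bad.clear(); stack.clear();
    is_bad.assign(tets.size(), 0);
    stack.push_back(seed); is_bad[seed] = 1;
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      bad.push_back(t);
      for (int f = 0; f < 4; ++f) {
        int u = tets[t].nb[f];
        if (u < 0 || is_bad[u] || !tets[u].alive) continue;
        double dx = qx - tets[u].cx, dy = qy - tets[u].cy, dz = qz - tets[u].cz;
        if (dx * dx + dy * dy + dz * dz < tets[u].r2) {
          is_bad[u] = 1;
          stack.push_back(u);
        }
      }
    }

    // boundary faces of the cavity -> new tets around ip
    std::map<std::pair<int, int>, std::pair<int, int>> open_edge;  // edge -> (tet, slot)
    std::vector<int> fresh;
    for (size_t b = 0; b < bad.size(); ++b) {
      int t = bad[b];
      for (int f = 0; f < 4; ++f) {
        int u = tets[t].nb[f];
        if (u >= 0 && is_bad[u]) continue;  // internal to cavity
        // face opposite slot f, oriented outward from tet t
        int a = tets[t].v[(f + 1) % 4], bb = tets[t].v[(f + 2) % 4],
            c = tets[t].v[(f + 3) % 4];
        Tet nt;
        nt.v[0] = ip; nt.v[1] = a; nt.v[2] = bb; nt.v[3] = c;
        if (orient3d(px, py, pz, nt.v[0], nt.v[1], nt.v[2], nt.v[3]) < 0)
          std::swap(nt.v[2], nt.v[3]);
        if (!circumsphere(px, py, pz, nt.v, nt.cx, nt.cy, nt.cz, nt.r2)) {
          nt.cx = nt.cy = nt.cz = 0; nt.r2 = std::numeric_limits<double>::infinity();
        }
        nt.alive = true;
        nt.nb[0] = u;  // across the old boundary face
        nt.nb[1] = nt.nb[2] = nt.nb[3] = -1;
        int id = (int)tets.size();
        tets.push_back(nt);
        fresh.push_back(id);
        if (u >= 0) {  // repoint the external neighbour at the new tet
          for (int g = 0; g < 4; ++g)
            if (tets[u].nb[g] == t) { tets[u].nb[g] = id; break; }
        }
        // stitch the three faces containing ip through shared edges
        for (int s = 1; s <= 3; ++s) {
          int e1 = tets[id].v[(s + 1) % 4 == 0 ? 1 : 0], e2;
          // face opposite slot s consists of the 3 verts != v[s]; it contains ip (v[0])
          int w[3]; int m = 0;
          for (int g = 0; g < 4; ++g) if (g != s) w[m++] = tets[id].v[g];
          // edge = the two non-ip vertices of that face
          int ea = -1, eb = -1;
          for (int g = 0; g < 3; ++g) {
            if (w[g] == ip) continue;
            if (ea < 0) ea = w[g]; else eb = w[g];
          }
          if (ea > eb) std::swap(ea, eb);
          (void)e1; (void)e2;
          auto key = std::make_pair(ea, eb);
          auto it = open_edge.find(key);
          if (it == open_edge.end()) {
            open_edge[key] = std::make_pair(id, s);
          } else {
            tets[id].nb[s] = it->second.first;
            tets[it->second.first].nb[it->second.second] = id;
            open_edge.erase(it);
          }
        }
      }
    }
    for (size_t b = 0; b < bad.size(); ++b) tets[bad[b]].alive = false;
    if (!open_edge.empty())
      stop("cavity stitching failed (numerically degenerate input)");
    (void)fresh;
  }

  // keep alive tets not touching super vertices
  int m = 0;
  for (size_t t = 0; t < tets.size(); ++t) {
    if (!tets[t].alive) continue;
    bool super = false;
    for (int f = 0; f < 4; ++f) if (tets[t].v[f] >= n) { super = true; break; }
    if (!super) ++m;
  }
  IntegerMatrix out(m, 4);
  int r = 0;
  for (size_t t = 0; t < tets.size(); ++t) {
    if (!tets[t].alive) continue;
    bool super = false;
    for (int f = 0; f < 4; ++f) if (tets[t].v[f] >= n) { super = true; break; }
    if (super) continue;
    for (int f = 0; f < 4; ++f) out(r, f) = tets[t].v[f] + 1;  // 1-based for R
    ++r;
  }
  return out;
}

// circumradius + volume of each tetrahedron on the *original* coordinates
// [[Rcpp::export]]
List tet_geometry_cpp(NumericMatrix pts, IntegerMatrix tets) {
  const int m = tets.nrow();
  const int n = pts.nrow();
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) { px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2); }
  NumericVector radius(m), volume(m);
  NumericMatrix center(m, 3);
  for (int t = 0; t < m; ++t) {
    int v[4] = { tets(t, 0) - 1, tets(t, 1) - 1, tets(t, 2) - 1, tets(t, 3) - 1 };
    double cx, cy, cz, r2;
    if (circumsphere(px, py, pz, v, cx, cy, cz, r2)) {
      radius[t] = std::sqrt(r2);
      center(t, 0) = cx; center(t, 1) = cy; center(t, 2) = cz;
    } else {
      radius[t] = R_PosInf;
      center(t, 0) = NA_REAL; center(t, 1) = NA_REAL; center(t, 2) = NA_REAL;
    }
    volume[t] = std::fabs(orient3d(px, py, pz, v[0], v[1], v[2], v[3])) / 6.0;
  }
  return List::create(_["circumradius"] = radius, _["volume"] = volume,
                      _["circumcenter"] = center);
}
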