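// Shortest-edge-collapse surface decimation with link-condition and
// normal-flip guards. Deterministic: ties broken on vertex indices.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <set>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct QEdge {
  double len;
  int u, v;        // u < v
  long stamp;      // sum of vertex versions at push time
  bool operator<(const QEdge& o) const {
    if (len != o.len) return len > o.len;  // min-heap via operator>
    if (u != o.u) return u > o.u;
    return v > o.v;
  }
};

inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

}  // namespace

// [[Rcpp::export]]
List decimate_mesh_cpp(NumericMatrix V, IntegerMatrix F, int target_faces) {
  const int nv = V.nrow(), nf = F.nrow();
  std::vector<double> X(3 * nv);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) X[3 * i + k] = V(i, k);
  std::vector<int> fv(3 * nf);
  std::vector<char> falive(nf, 1), valive(nv, 1);
  std::vector<long> vstamp(nv, 0);
  std::vector<std::set<int>> vfaces(nv);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) {
      fv[3 * f + k] = F(f, k) - 1;
      vfaces[fv[3 * f + k]].insert(f);
    }
  int live_faces = nf;

  auto edge_len = [&](int a, int b) {
    double s = 0;
    for (int k = 0; k < 3; ++k) {
      double d = X[3 * a + k] - X[3 * b + k];
      s += d * d;
    }
    return std::sqrt(s);
  };
  auto face_normal = [&](int f, const double* moved_pos, int moved_vtx, double* nrm) {
    double p[3][3];
    for (int k = 0; k < 3; ++k) {
      int vv = fv[3 * f + k];
      const double* src = (vv == moved_vtx && moved_pos) ? moved_pos : &X[3 * vv];
      for (int d = 0; d < 3; ++d) p[k][d] = src[d];
    }
    double e1[3], e2[3];
    for (int d = 0; d < 3; ++d) { e1[d] = p[1][d] - p[0][d]; e2[d] = p[2][d] - p[0][d]; }
    cross3(e1, e2, nrm);
  };

  std::priority_queue<QEdge> pq;
  auto push_edges_of = [&](int u) {
    std::set<int> nbrs;
    for (int f : vfaces[u])
      for (int k = 0; k < 3; ++k) {
        int w = fv[3 * f + k];
        if (w != u) nbrs.insert(w);
      }
    for (int w : nbrs) {
      QEdge e;
      e.u = std::min(u, w); e.v = std::max(u, w);
      e.len = edge_len(e.u, e.v);
      e.stamp = vstamp[e.u] + vstamp[e.v];
      pq.push(e);
    }
  };
  for (int u = 0; u < nv; ++u) push_edges_of(u);

  while (live_faces > target_faces && !pq.empty()) {
    QEdge e = pq.top(); pq.pop();
    int u = e.u, v = e.v;
    if (!valive[u] || !valive[v]) continue;
    if (e.stamp != vstamp[u] + vstamp[v]) continue;  // stale
    // still an edge?
    std::vector<int> shared;
    for (int f : vfaces[u]) if (vfaces[v].count(f)) shared.push_back(f);
    if (shared.empty()) continue;

    // link condition: vertices adjacent to both u and v must be exactly the
    // opposite vertices of the shared faces
    std::set<int> nu, nvv;
    for (int f : vfaces[u]) for (int k = 0; k < 3; ++k) { int w = fv[3 * f + k]; if (w != u) nu.insert(w); }
    for (int f : vfaces[v]) for (int k = 0; k < 3; ++k) { int w = fv[3 * f + k]; if (w != v) nvv.insert(w); }
    std::vector<int> common;
    std::set_intersection(nu.begin(), nu.end(), nvv.begin(), nvv.end(),
                          std::back_inserter(common));
    std::set<int> opp;
    for (int f : shared)
      for (int k = 0; k < 3; ++k) {
        int w = fv[3 * f + k];
        if (w != u && w != v) opp.insert(w);
      }
    bool ok = common.size() == opp.size();
    if (ok) for (int w : common) if (!opp.count(w)) { ok = false; break; }
    if (!ok) continue;

    double mid[3];
    for (int k = 0; k < 3; ++k) mid[k] = 0.5 * (X[3 * u + k] + X[3 * v + k]);

    // reject collapses that flip a surviving face's normal
    bool flip = false;
    for (int who = 0; who < 2 && !flip; ++who) {
      int a = who == 0 ? u : v;
      for (int f : vfaces[a]) {
        bool is_shared = false;
        for (int sf : shared) if (sf == f) { is_shared = true; break; }
        if (is_shared) continue;
        double n0[3], n1[3];
        face_normal(f, nullptr, -1, n0);
        // after collapse both u and v sit at mid; face contains exactly one of them
        face_normal(f, mid, a, n1);
        double dot = n0[0] * n1[0] + n0[1] * n1[1] + n0[2] * n1[2];
        double a1 = std::sqrt(n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2]);
        if (dot <= 0.0 || a1 < 1e-300) { flip = true; break; }
      }
    }
    if (flip) continue;

    // apply: v merges into u at the midpoint
    for (int k = 0; k < 3; ++k) X[3 * u + k] = mid[k];
    for (int f : shared) {
      if (falive[f]) { falive[f] = 0; --live_faces; }
      for (int k = 0; k < 3; ++k) vfaces[fv[3 * f + k]].erase(f);
    }
    std::vector<int> vf(vfaces[v].begin(), vfaces[v].end());
    for (int f : vf) {
      for (int k = 0; k < 3; ++k) if (fv[3 * f + k] == v) fv[3 * f + k] = u;
      vfaces[v].erase(f);
      vfaces[u].insert(f);
    }
    valive[v] = 0;
    ++vstamp[u];
    push_edges_of(u);
  }

  // compact
  std::vector<int> vmap(nv, -1);
  int nvo = 0;
  for (int i = 0; i < nv; ++i)
    if (valive[i] && !vfaces[i].empty()) vmap[i] = nvo++;
  int nfo = 0;
  for (int f = 0; f < nf; ++f) if (falive[f]) ++nfo;
  NumericMatrix Vo(nvo, 3);
  for (int i = 0; i < nv; ++i)
    if (vmap[i] >= 0)
      for (int k = 0; k < 3; ++k) Vo(vmap[i], k) = X[3 * i + k];
  IntegerMatrix Fo(nfo, 3);
  int r = 0;
  for (int f = 0; f < nf; ++f) {
    if (!falive[f]) continue;
    for (int k = 0; k < 3; ++k) Fo(r, k) = vmap[fv[3 * f + k]] + 1;
    ++r;
  }
  return List::create(_["vertices"] = Vo, _["faces"] = Fo);
}
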