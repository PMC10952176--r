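// Per-vertex surface-variation energy: Gaussian-weighted covariance of
// neighbour positions within a cutoff radius; energy = lambda1 / sum(lambda).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

inline long long cell_key(int ix, int iy, int iz) {
  return ((long long)(ix + 1048576) << 42) |
         ((long long)(iy + 1048576) << 21) |
         (long long)(iz + 1048576);
}

// smallest eigenvalue ratio lambda_min / trace of a symmetric 3x3 matrix,
// by the closed-form trigonometric solution (Smith's method)
double min_eig_ratio(double a11, double a12, double a13,
                     double a22, double a23, double a33) {
  const double tr = a11 + a22 + a33;
  if (tr <= 0) return 0.0;
  const double q = tr / 3.0;
  const double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
  const double p2 = b11 * b11 + b22 * b22 + b33 * b33 +
                    2.0 * (a12 * a12 + a13 * a13 + a23 * a23);
  if (p2 <= 1e-300) return 1.0 / 3.0;  // isotropic
  const double p = std::sqrt(p2 / 6.0);
  // det(B) / p^3 / 2
  const double detB = b11 * (b22 * b33 - a23 * a23) -
                      a12 * (a12 * b33 - a23 * a13) +
                      a13 * (a12 * a23 - b22 * a13);
  double r = detB / (2.0 * p * p * p);
  r = std::max(-1.0, std::min(1.0, r));
  const double phi = std::acos(r) / 3.0;
  // smallest eigenvalue
  const double lmin = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  return std::max(0.0, lmin) / tr;
}

}  // namespace

// [[Rcpp::export]]
List vertex_energy_cpp(NumericMatrix V, double eps) {
  const int n = V.nrow();
  const double cutoff = eps * std::sqrt(std::log(1e9));  // w < 1e-9 beyond
  const double cut2 = cutoff * cutoff;
  const double inv_eps2 = 1.0 / (eps * eps);

  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = V(i, 0); Y[i] = V(i, 1); Z[i] = V(i, 2); }

  std::unordered_map<long long, std::vector<int>> grid;
  grid.reserve(2 * n);
  auto idx = [&](double x) { return (int)std::floor(x / cutoff); };
  for (int i = 0; i < n; ++i)
    grid[cell_key(idx(X[i]), idx(Y[i]), idx(Z[i]))].push_back(i);

  NumericVector energy(n);
  int starved = 0;
  for (int i = 0; i < n; ++i) {
    const double xi = X[i], yi = Y[i], zi = Z[i];
    int cx = idx(xi), cy = idx(yi), cz = idx(zi);
    int count = 0;
    double sw = 0, sx = 0, sy = 0, sz = 0;
    double sxx = 0, sxy = 0, sxz = 0, syy = 0, syz = 0, szz = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cell_key(cx + dx, cy + dy, cz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            const double ddx = X[j] - xi, ddy = Y[j] - yi, ddz = Z[j] - zi;
            const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 > cut2) continue;
            ++count;
            const double w = std::exp(-d2 * inv_eps2);
            sw += w;
            sx += w * X[j]; sy += w * Y[j]; sz += w * Z[j];
            sxx += w * X[j] * X[j]; sxy += w * X[j] * Y[j]; sxz += w * X[j] * Z[j];
            syy += w * Y[j] * Y[j]; syz += w * Y[j] * Z[j]; szz += w * Z[j] * Z[j];
          }
        }
    if (count < 4) { energy[i] = 0.0; ++starved; continue; }
    const double mx = sx / sw, my = sy / sw, mz = sz / sw;
    energy[i] = min_eig_ratio(sxx / sw - mx * mx, sxy / sw - mx * my,
                              sxz / sw - mx * mz, syy / sw - my * my,
                              syz / sw - my * mz, szz / sw - mz * mz);
  }
  return List::create(_["energy"] = energy, _["n_starved"] = starved);
}
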