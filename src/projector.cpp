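#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Exact ray/pixel intersection lengths for a parallel-beam geometry.
//
// The image square is centred at the origin with half-width
// h = side * pixel_size / 2.  Array row r (0-based, top row first) spans
// y in [h - (r+1)*px, h - r*px]; column c spans x in [-h + c*px, -h + (c+1)*px].
// A ray of view angle theta (radians) and detector offset t passes through
// the point (t cos(theta), t sin(theta)) with unit direction
// (-sin(theta), cos(theta)), so that t = x cos(theta) + y sin(theta) along
// the ray.  Pixels are flattened row-major: flat = r * side + c.
//
// Traversal collects every parameter value at which the ray crosses a grid
// line, sorts them, and assigns the chord length between consecutive
// crossings to the pixel containing the midpoint (a Siddon-style sweep,
// exact for the indicator pixel basis).

// [[Rcpp::export(name = ".trace_system_matrix")]]
List trace_system_matrix(int side, double pixel_size,
                         NumericVector angles_rad,
                         int n_detectors, double detector_spacing) {
  const double h = 0.5 * side * pixel_size;
  const int n_views = angles_rad.size();
  const double eps = 1e-12;

  std::vector<int> out_i;     // ray index (0-based)
  std::vector<int> out_j;     // pixel index (0-based, row-major)
  std::vector<double> out_x;  // chord length

  std::vector<double> ts;
  ts.reserve(2 * side + 4);

  for (int v = 0; v < n_views; ++v) {
    const double ct = std::cos(angles_rad[v]);
    const double st = std::sin(angles_rad[v]);
    const double dx = -st, dy = ct;
    for (int k = 0; k < n_detectors; ++k) {
      const double t = (k - (n_detectors - 1) / 2.0) * detector_spacing;
      const double px0 = t * ct, py0 = t * st;
      // slab clipping against [-h, h]^2
      double tmin = -std::numeric_limits<double>::infinity();
      double tmax = std::numeric_limits<double>::infinity();
      bool miss = false;
      if (std::fabs(dx) > eps) {
        double a = (-h - px0) / dx, b = (h - px0) / dx;
        if (a > b) std::swap(a, b);
        tmin = std::max(tmin, a);
        tmax = std::min(tmax, b);
      } else if (px0 < -h || px0 > h) {
        miss = true;
      }
      if (!miss && std::fabs(dy) > eps) {
        double a = (-h - py0) / dy, b = (h - py0) / dy;
        if (a > b) std::swap(a, b);
        tmin = std::max(tmin, a);
        tmax = std::min(tmax, b);
      } else if (!miss && std::fabs(dy) <= eps && (py0 < -h || py0 > h)) {
        miss = true;
      }
      if (miss || tmax - tmin <= eps) continue;

      ts.clear();
      ts.push_back(tmin);
      ts.push_back(tmax);
      if (std::fabs(dx) > eps) {
        for (int g = 0; g <= side; ++g) {
          const double xg = -h + g * pixel_size;
          const double tg = (xg - px0) / dx;
          if (tg > tmin + eps && tg < tmax - eps) ts.push_back(tg);
        }
      }
      if (std::fabs(dy) > eps) {
        for (int g = 0; g <= side; ++g) {
          const double yg = -h + g * pixel_size;
          const double tg = (yg - py0) / dy;
          if (tg > tmin + eps && tg < tmax - eps) ts.push_back(tg);
        }
      }
      std::sort(ts.begin(), ts.end());

      const int ray = v * n_detectors + k;
      for (size_t s = 0; s + 1 < ts.size(); ++s) {
        const double len = ts[s + 1] - ts[s];
        if (len <= eps) continue;
        const double tm = 0.5 * (ts[s] + ts[s + 1]);
        const double mx = px0 + tm * dx, my = py0 + tm * dy;
        int c = (int)std::floor((mx + h) / pixel_size);
        int r = (int)std::floor((h - my) / pixel_size);
        if (c < 0) c = 0;
        if (c >= side) c = side - 1;
        if (r < 0) r = 0;
        if (r >= side) r = side - 1;
        out_i.push_back(ray);
        out_j.push_back(r * side + c);
        out_x.push_back(len);
      }
    }
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["x"] = wrap(out_x));
}

// Kaczmarz (ART) sweeps on a CSR matrix.  Rows with zero norm are skipped.
// Returns the iterate after n_sweeps full sweeps and the residual 2-norm
// recorded after each sweep.

// [[Rcpp::export(name = ".art_sweeps")]]
List art_sweeps(IntegerVector row_ptr, IntegerVector col_idx,
                NumericVector vals, NumericVector b, NumericVector x0,
                double lambda, int n_sweeps, bool nonneg) {
  const int m = b.size();
  const int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end());

  std::vector<double> row_norm2(m);
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int p = row_ptr[i]; p < row_ptr[i + 1]; ++p) s += vals[p] * vals[p];
    row_norm2[i] = s;
  }

  NumericVector resid(n_sweeps);
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int i = 0; i < m; ++i) {
      if (row_norm2[i] <= 0.0) continue;
      double dot = 0.0;
      for (int p = row_ptr[i]; p < row_ptr[i + 1]; ++p)
        dot += vals[p] * x[col_idx[p]];
      const double c = lambda * (b[i] - dot) / row_norm2[i];
      for (int p = row_ptr[i]; p < row_ptr[i + 1]; ++p)
        x[col_idx[p]] += c * vals[p];
    }
    if (nonneg)
      for (int j = 0; j < n; ++j)
        if (x[j] < 0.0) x[j] = 0.0;
    double r2 = 0.0;
    for (int i = 0; i < m; ++i) {
      double dot = 0.0;
      for (int p = row_ptr[i]; p < row_ptr[i + 1]; ++p)
        dot += vals[p] * x[col_idx[p]];
      const double d = dot - b[i];
      r2 += d * d;
    }
    resid[sweep] = std::sqrt(r2);
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["residual"] = resid);
}
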