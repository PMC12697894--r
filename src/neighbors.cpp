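#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Uniform grid binning over points: cell index for (x, y) given origin and cell size.
struct Grid {
  double x0, y0, cell;
  int nx, ny;
  std::vector<std::vector<int>> bins; // 0-based point indices per cell

  Grid(const NumericVector& x, const NumericVector& y, double cell_size,
       double xmin, double xmax, double ymin, double ymax) {
    cell = cell_size;
    x0 = xmin; y0 = ymin;
    nx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
    ny = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);
    bins.resize((size_t)nx * ny);
    for (int i = 0; i < x.size(); ++i) {
      int cx = (int)std::floor((x[i] - x0) / cell);
      int cy = (int)std::floor((y[i] - y0) / cell);
      cx = std::min(std::max(cx, 0), nx - 1);
      cy = std::min(std::max(cy, 0), ny - 1);
      bins[(size_t)cy * nx + cx].push_back(i);
    }
  }
  inline int cx_of(double x) const {
    return std::min(std::max((int)std::floor((x - x0) / cell), 0), nx - 1);
  }
  inline int cy_of(double y) const {
    return std::min(std::max((int)std::floor((y - y0) / cell), 0), ny - 1);
  }
};

// Actual competition received by each focal colony from source colonies.
// Sources exert strength[i] * (1 - d / radius[i]) within their own radius.
// Cross-form and cross-species multipliers are applied per ordered pair.
// [[Rcpp::export]]
NumericVector cpp_competition(NumericVector sx, NumericVector sy,
                              NumericVector strength, NumericVector radius,
                              IntegerVector s_form, IntegerVector s_species,
                              IntegerVector s_id,
                              NumericVector rx, NumericVector ry,
                              IntegerVector r_form, IntegerVector r_species,
                              IntegerVector r_id,
                              double poly_pair_coeff,
                              double f_native_on_fire, double f_fire_on_native) {
  int ns = sx.size(), nr = rx.size();
  NumericVector out(nr, 0.0);
  if (ns == 0 || nr == 0) return out;
  double maxr = 0.0;
  for (int i = 0; i < ns; ++i) maxr = std::max(maxr, radius[i]);
  if (maxr <= 0) return out;
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < ns; ++i) {
    xmin = std::min(xmin, sx[i]); xmax = std::max(xmax, sx[i]);
    ymin = std::min(ymin, sy[i]); ymax = std::max(ymax, sy[i]);
  }
  Grid g(sx, sy, maxr, xmin, xmax, ymin, ymax);
  for (int j = 0; j < nr; ++j) {
    double xj = rx[j], yj = ry[j];
    int cx = g.cx_of(xj), cy = g.cy_of(yj);
    double acc = 0.0;
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = cy + dy; if (yy < 0 || yy >= g.ny) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = cx + dx; if (xx < 0 || xx >= g.nx) continue;
        const std::vector<int>& cellv = g.bins[(size_t)yy * g.nx + xx];
        for (size_t k = 0; k < cellv.size(); ++k) {
          int i = cellv[k];
          if (s_id[i] == r_id[j]) continue;
          double ddx = sx[i] - xj, ddy = sy[i] - yj;
          double d = std::sqrt(ddx * ddx + ddy * ddy);
          if (d >= radius[i]) continue;
          double w = strength[i] * (1.0 - d / radius[i]);
          if (s_form[i] == 2 && r_form[j] == 2) w *= poly_pair_coeff;
          if (s_species[i] != r_species[j]) {
            // species 1 = fire ant, species 2 = native
            w *= (s_species[i] == 2) ? f_native_on_fire : f_fire_on_native;
          }
          acc += w;
        }
      }
    }
    out[j] = acc;
  }
  return out;
}

// Weighted mate sampling: for each queen, draw `attempts` candidate fathers
// (with replacement) from fathers within `radius[q]`, probability proportional
// to weight.  Falls back to the k nearest fathers when the disc is empty.
// Returns a 1-based index matrix (0 where no father exists at all).
// [[Rcpp::export]]
IntegerMatrix cpp_mate_sample(NumericVector qx, NumericVector qy,
                              NumericVector radius,
                              NumericVector fx, NumericVector fy,
                              NumericVector weight,
                              int attempts, int fallback_k) {
  int nq = qx.size(), nf = fx.size();
  IntegerMatrix out(nq, attempts);
  if (nq == 0) return out;
  if (nf == 0) { std::fill(out.begin(), out.end(), 0); return out; }
  double maxr = 0.0;
  for (int q = 0; q < nq; ++q) maxr = std::max(maxr, radius[q]);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < nf; ++i) {
    xmin = std::min(xmin, fx[i]); xmax = std::max(xmax, fx[i]);
    ymin = std::min(ymin, fy[i]); ymax = std::max(ymax, fy[i]);
  }
  double cell = maxr > 0 ? maxr : std::max(xmax - xmin, ymax - ymin) + 1.0;
  Grid g(fx, fy, cell, xmin, xmax, ymin, ymax);
  std::vector<int> cand;
  std::vector<double> cdist;
  for (int q = 0; q < nq; ++q) {
    double r = radius[q];
    cand.clear();
    int cx = g.cx_of(qx[q]), cy = g.cy_of(qy[q]);
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = cy + dy; if (yy < 0 || yy >= g.ny) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = cx + dx; if (xx < 0 || xx >= g.nx) continue;
        const std::vector<int>& cellv = g.bins[(size_t)yy * g.nx + xx];
        for (size_t k = 0; k < cellv.size(); ++k) {
          int i = cellv[k];
          double ddx = fx[i] - qx[q], ddy = fy[i] - qy[q];
          if (ddx * ddx + ddy * ddy <= r * r) cand.push_back(i);
        }
      }
    }
    if (cand.empty() && fallback_k > 0) {
      // nearest-k fallback: expand square rings of cells until the k-th best
      // distance is certified
      cand.clear(); cdist.clear();
      int ring = 0;
      double kth = R_PosInf;
      int maxring = std::max(g.nx, g.ny);
      while (ring <= maxring) {
        bool any_cell = false;
        for (int dy = -ring; dy <= ring; ++dy) {
          int yy = cy + dy; if (yy < 0 || yy >= g.ny) continue;
          for (int dx = -ring; dx <= ring; ++dx) {
            if (std::max(std::abs(dx), std::abs(dy)) != ring) continue;
            int xx = cx + dx; if (xx < 0 || xx >= g.nx) continue;
            any_cell = true;
            const std::vector<int>& cellv = g.bins[(size_t)yy * g.nx + xx];
            for (size_t k = 0; k < cellv.size(); ++k) {
              int i = cellv[k];
              double ddx = fx[i] - qx[q], ddy = fy[i] - qy[q];
              cand.push_back(i);
              cdist.push_back(std::sqrt(ddx * ddx + ddy * ddy));
            }
          }
        }
        if ((int)cand.size() >= fallback_k || !any_cell) {
          // certified when ring lower bound exceeds current k-th distance
          if ((int)cand.size() >= fallback_k) {
            std::vector<int> ord(cand.size());
            for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
            int kk = std::min<int>(fallback_k, (int)cand.size());
            std::nth_element(ord.begin(), ord.begin() + kk - 1, ord.end(),
                             [&](int a, int b) { return cdist[a] < cdist[b]; });
            kth = cdist[ord[kk - 1]];
          }
          double ring_lb = (double)ring * g.cell;
          if (ring_lb > kth || ring >= maxring) break;
        }
        ++ring;
      }
      if (!cand.empty() && (int)cand.size() > fallback_k) {
        std::vector<int> ord(cand.size());
        for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
        std::nth_element(ord.begin(), ord.begin() + fallback_k - 1, ord.end(),
                         [&](int a, int b) { return cdist[a] < cdist[b]; });
        std::vector<int> kept;
        for (int i = 0; i < fallback_k; ++i) kept.push_back(cand[ord[i]]);
        cand.swap(kept);
      }
    }
    if (cand.empty()) {
      for (int a = 0; a < attempts; ++a) out(q, a) = 0;
      continue;
    }
    double wmax = 0.0, wsum = 0.0;
    for (size_t k = 0; k < cand.size(); ++k) {
      wmax = std::max(wmax, weight[cand[k]]);
      wsum += weight[cand[k]];
    }
    if (wmax <= 0) { // all zero-weight: no selectable father
      for (int a = 0; a < attempts; ++a) out(q, a) = 0;
      continue;
    }
    int m = (int)cand.size();
    for (int a = 0; a < attempts; ++a) {
      int pick = -1;
      for (int it = 0; it < 1000; ++it) {
        int i = (int)(unif_rand() * m); if (i >= m) i = m - 1;
        if (unif_rand() * wmax <= weight[cand[i]]) { pick = cand[i]; break; }
      }
      if (pick < 0) { // numeric fallback: cumulative-sum draw
        double u = unif_rand() * wsum, c = 0.0;
        pick = cand[m - 1];
        for (int i = 0; i < m; ++i) {
          c += weight[cand[i]];
          if (u <= c) { pick = cand[i]; break; }
        }
      }
      out(q, a) = pick + 1;
    }
  }
  return out;
}

// Nearest-neighbor distance for every point (Clark-Evans ingredient).
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericVector x, NumericVector y) {
  int n = x.size();
  NumericVector out(n, R_PosInf);
  if (n < 2) return out;
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) { std::fill(out.begin(), out.end(), 0.0); return out; }
  double cell = span / std::max(1.0, std::sqrt((double)n));
  Grid g(x, y, cell, xmin, xmax, ymin, ymax);
  for (int j = 0; j < n; ++j) {
    int cx = g.cx_of(x[j]), cy = g.cy_of(y[j]);
    double best = R_PosInf;
    int maxring = std::max(g.nx, g.ny);
    for (int ring = 0; ring <= maxring; ++ring) {
      double ring_lb = (double)(ring - 1) * g.cell;
      if (ring > 0 && ring_lb > best) break;
      for (int dy = -ring; dy <= ring; ++dy) {
        int yy = cy + dy; if (yy < 0 || yy >= g.ny) continue;
        for (int dx = -ring; dx <= ring; ++dx) {
          if (std::max(std::abs(dx), std::abs(dy)) != ring) continue;
          int xx = cx + dx; if (xx < 0 || xx >= g.nx) continue;
          const std::vector<int>& cellv = g.bins[(size_t)yy * g.nx + xx];
          for (size_t k = 0; k < cellv.size(); ++k) {
            int i = cellv[k];
            if (i == j) continue;
            double ddx = x[i] - x[j], ddy = y[i] - y[j];
            double d = std::sqrt(ddx * ddx + ddy * ddy);
            if (d < best) best = d;
          }
        }
      }
    }
    out[j] = best;
  }
  return out;
}
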