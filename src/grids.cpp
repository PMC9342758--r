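#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static const double DT_INF = 1e20;

// 1-D squared distance transform of sampled function f
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact center-to-center Euclidean distance (in cell units) to the nearest
// TRUE cell of `mask`. Cells that are TRUE get 0.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<double> g(nr * nc);
  // column pass
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; c++) {
    for (int r = 0; r < nr; r++) f[r] = mask(r, c) ? 0.0 : DT_INF;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; r++) g[(size_t)c * nr + r] = d[r];
  }
  // row pass
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) f[c] = g[(size_t)c * nr + r];
    dt1d(f, d, nc);
    for (int c = 0; c < nc; c++) out(r, c) = std::sqrt(d[c]);
  }
  return out;
}

// ---- moving-window Shannon evenness ----

// classes coded 1..K; evenness over cells whose centers fall within
// radius_cells of the focal cell center, clipped at map edges.
// [[Rcpp::export]]
NumericMatrix cpp_evenness(IntegerMatrix cls, double radius_cells, int K) {
  int nr = cls.nrow(), nc = cls.ncol();
  double r2 = radius_cells * radius_cells;
  int R = (int)std::floor(radius_cells);
  std::vector<int> offr, offc;
  for (int dr = -R; dr <= R; dr++)
    for (int dc = -R; dc <= R; dc++)
      if ((double)dr * dr + (double)dc * dc <= r2) {
        offr.push_back(dr);
        offc.push_back(dc);
      }
  int m = (int)offr.size();
  double logK = std::log((double)K);
  NumericMatrix out(nr, nc);
  std::vector<int> cnt(K);
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      std::fill(cnt.begin(), cnt.end(), 0);
      int tot = 0;
      for (int t = 0; t < m; t++) {
        int rr = r + offr[t], cc = c + offc[t];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        cnt[cls(rr, cc) - 1]++;
        tot++;
      }
      double he = 0.0;
      for (int k = 0; k < K; k++) {
        if (cnt[k] > 0) {
          double p = (double)cnt[k] / tot;
          he -= p * std::log(p);
        }
      }
      out(r, c) = he / logK;
    }
  }
  return out;
}

// ---- distance from cell centers to polyline segments ----

// segs: one row per segment (x1, y1, x2, y2); cell centers at
// (x0 + (c+0.5)*cs, y0 + (r+0.5)*cs), grid row 0 = bottom row of matrix? No:
// matrix row i corresponds to grid row i-1 counted from the bottom (the R
// wrapper owns that convention; here row r means matrix row r).
// [[Rcpp::export]]
NumericMatrix cpp_dist_segments(int nrow, int ncol, double x0, double y0,
                                double cs, NumericMatrix segs) {
  int ns = segs.nrow();
  NumericMatrix out(nrow, ncol);
  for (int r = 0; r < nrow; r++) {
    double py = y0 + (r + 0.5) * cs;
    for (int c = 0; c < ncol; c++) {
      double px = x0 + (c + 0.5) * cs;
      double best = std::numeric_limits<double>::infinity();
      for (int s = 0; s < ns; s++) {
        double ax = segs(s, 0), ay = segs(s, 1), bx = segs(s, 2), by = segs(s, 3);
        double dx = bx - ax, dy = by - ay;
        double len2 = dx * dx + dy * dy;
        double t = 0.0;
        if (len2 > 0) {
          t = ((px - ax) * dx + (py - ay) * dy) / len2;
          if (t < 0) t = 0;
          if (t > 1) t = 1;
        }
        double qx = ax + t * dx - px, qy = ay + t * dy - py;
        double d2 = qx * qx + qy * qy;
        if (d2 < best) best = d2;
      }
      out(r, c) = std::sqrt(best);
    }
  }
  return out;
}

// ---- connected components (4-neighbour) of equal-valued cells ----

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix cls) {
  int nr = cls.nrow(), nc = cls.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int r0 = 0; r0 < nr; r0++) {
    for (int c0 = 0; c0 < nc; c0++) {
      if (lab(r0, c0) != 0) continue;
      next++;
      int v = cls(r0, c0);
      lab(r0, c0) = next;
      stack.clear();
      stack.push_back(r0 * nc + c0);
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int r = cur / nc, c = cur % nc;
        const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
        for (int t = 0; t < 4; t++) {
          int rr = r + dr[t], cc = c + dc[t];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (lab(rr, cc) == 0 && cls(rr, cc) == v) {
            lab(rr, cc) = next;
            stack.push_back(rr * nc + cc);
          }
        }
      }
    }
  }
  return lab;
}

// ---- kernel functionals for the direct plug-in bandwidth ----

// psi_r estimator: n^-2 * sum_{i,j} phi_g^{(r)}(x_i - x_j), Gaussian kernel,
// r in {4, 6}; diagonal terms included.
// [[Rcpp::export]]
double cpp_psi(NumericVector x, double g, int r) {
  int n = x.size();
  double inv = 1.0 / g;
  double norm = std::pow(inv, r + 1);
  const double c0 = 0.3989422804014327; // 1/sqrt(2*pi)
  double diag_poly = (r == 4) ? 3.0 : -15.0;
  double total = (double)n * norm * diag_poly * c0; // u = 0 terms
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      double t = (x[i] - x[j]) * inv;
      double t2 = t * t;
      double poly;
      if (r == 4)
        poly = (t2 * t2 - 6.0 * t2 + 3.0);
      else
        poly = (t2 * t2 * t2 - 15.0 * t2 * t2 + 45.0 * t2 - 15.0);
      total += 2.0 * norm * poly * c0 * std::exp(-0.5 * t2);
    }
  }
  return total / ((double)n * (double)n);
}
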