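#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// largest integer k >= 0 with k*k <= rem (exact; no floating slop for the
// magnitudes used here, since k*k is exactly representable)
static inline int isqrt_le(double rem) {
  int k = (int)std::floor(std::sqrt(rem));
  while ((double)(k + 1) * (k + 1) <= rem) ++k;
  while (k > 0 && (double)k * k > rem) --k;
  return k;
}

// sum p[a..b] inclusive with 4 independent accumulators; the grouping is
// relative to the range start, so for a given set of summed cells the
// result is identical no matter how the grid was windowed (tiling safety)
static inline double sum_range(const double *p, int a, int b, long &n) {
  double s0 = 0, s1 = 0, s2 = 0, s3 = 0;
  int i = a;
  for (; i + 3 <= b; i += 4) {
    s0 += p[i]; s1 += p[i + 1]; s2 += p[i + 2]; s3 += p[i + 3];
  }
  for (; i <= b; ++i) s0 += p[i];
  if (b >= a) n += b - a + 1;
  return (s0 + s1) + (s2 + s3);
}

// Focal disk / annulus sum.
//
// For every cell, sums input values over the integer offsets (dc, dr) with
// q_in < dc^2 + dr^2 <= q_out, where q = (radius / cell_size)^2. A plain
// disk uses q_in < 0. Membership is by cell-centre distance with a closed
// outer comparison (ties at exactly the radius are included), decided in
// exact arithmetic. Cells outside the matrix contribute nothing (zero
// padding), so a kernel lying entirely off-grid sums to 0; NA cells
// contribute 0 but are tracked, so a neighbourhood whose in-grid cells are
// all NA yields NA.
//
// Results are strictly per cell (offsets visited in a fixed order relative
// to the focal cell), so any tiling of the grid with overlap >= the kernel
// half-width reproduces the untiled output bit for bit.
// [[Rcpp::export]]
NumericMatrix focal_disk_sum_cpp(NumericMatrix x, double q_in, double q_out) {
  const int nr = x.nrow(), nc = x.ncol();
  const int k = isqrt_le(q_out);
  NumericMatrix out(nr, nc);
  const double *xp = REAL(x);
  bool has_na = false;
  for (R_xlen_t i = 0; i < (R_xlen_t)nr * nc; ++i)
    if (ISNAN(xp[i])) { has_na = true; break; }
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      long nvis = 0, ngrid = 0;
      const int dc0 = std::max(-k, -c), dc1 = std::min(k, nc - 1 - c);
      for (int dc = dc0; dc <= dc1; ++dc) {
        const double dc2 = (double)dc * dc;
        const double rem = q_out - dc2;
        if (rem < 0) continue;
        const int kd = isqrt_le(rem);
        // annulus: exclude |dr| <= kin where dr^2 <= q_in - dc^2
        const int kin = (q_in >= dc2) ? isqrt_le(q_in - dc2) : -1;
        const int dr0 = std::max(-kd, -r), dr1 = std::min(kd, nr - 1 - r);
        if (dr0 > dr1) continue;
        const double *col = xp + (size_t)(c + dc) * nr + r;
        if (has_na) {
          for (int dr = dr0; dr <= dr1; ++dr) {
            if (dr >= -kin && dr <= kin) continue;
            ++ngrid;
            const double v = col[dr];
            if (!ISNAN(v)) { acc += v; ++nvis; }
          }
        } else if (kin < 0) {
          acc += sum_range(col, dr0, dr1, nvis);
        } else {
          acc += sum_range(col, dr0, std::min(dr1, -kin - 1), nvis);
          acc += sum_range(col, std::max(dr0, kin + 1), dr1, nvis);
        }
      }
      if (!has_na) ngrid = nvis;
      out(r, c) = (ngrid > 0 && nvis == 0) ? NA_REAL : acc;
    }
  }
  return out;
}

// Minimum Euclidean distance from each query point to a set of line
// segments (exact point-to-segment geometry, brute force over segments).
// [[Rcpp::export]]
NumericVector min_dist_point_segments_cpp(NumericVector px, NumericVector py,
                                          NumericVector x1, NumericVector y1,
                                          NumericVector x2, NumericVector y2) {
  const R_xlen_t np = px.size(), ns = x1.size();
  NumericVector best(np, R_PosInf);
  for (R_xlen_t s = 0; s < ns; ++s) {
    const double ax = x1[s], ay = y1[s];
    const double dx = x2[s] - ax, dy = y2[s] - ay;
    const double len2 = dx * dx + dy * dy;
    for (R_xlen_t i = 0; i < np; ++i) {
      double t = 0.0;
      if (len2 > 0.0) {
        t = ((px[i] - ax) * dx + (py[i] - ay) * dy) / len2;
        if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      }
      const double ex = px[i] - (ax + t * dx), ey = py[i] - (ay + t * dy);
      const double d2 = ex * ex + ey * ey;
      if (d2 < best[i] * best[i]) best[i] = std::sqrt(d2);
    }
  }
  return best;
}

// Inverse-distance-weighted interpolation of station values onto a grid.
// Weights are d^(-power) over stations with d <= radius; a cell whose
// centre lies within snap_dist of a station takes the nearest such
// station's value exactly; cells with no station within the radius are NA.
// [[Rcpp::export]]
NumericMatrix idw_grid_cpp(int n_rows, int n_cols, double x_min, double y_max,
                           double cell_size, NumericVector sx, NumericVector sy,
                           NumericVector sv, double radius, double power,
                           double snap_dist) {
  NumericMatrix out(n_rows, n_cols);
  const R_xlen_t ns = sx.size();
  for (int c = 0; c < n_cols; ++c) {
    const double cx = x_min + (c + 0.5) * cell_size;
    for (int r = 0; r < n_rows; ++r) {
      const double cy = y_max - (r + 0.5) * cell_size;
      double num = 0.0, den = 0.0;
      double d_near = R_PosInf, v_near = NA_REAL;
      for (R_xlen_t s = 0; s < ns; ++s) {
        const double dx = cx - sx[s], dy = cy - sy[s];
        const double d = std::sqrt(dx * dx + dy * dy);
        if (d < d_near) { d_near = d; v_near = sv[s]; }
        if (d <= radius && d > 0.0) {
          const double w = std::pow(d, -power);
          num += w * sv[s];
          den += w;
        }
      }
      if (d_near < snap_dist)
        out(r, c) = v_near;
      else if (den > 0.0)
        out(r, c) = num / den;
      else
        out(r, c) = NA_REAL;
    }
  }
  return out;
}
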