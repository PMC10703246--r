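// Pixel-level primitives: polygon rasterization with an inclusive boundary
// rule, and 26-neighborhood local maxima in a (row, col, scale) volume.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Point-on-segment test in continuous pixel coordinates.
static bool on_segment(double px, double py, double x1, double y1,
                       double x2, double y2) {
  const double cross = (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1);
  if (std::fabs(cross) > 1e-9) return false;
  if (px < std::min(x1, x2) - 1e-9 || px > std::max(x1, x2) + 1e-9)
    return false;
  if (py < std::min(y1, y2) - 1e-9 || py > std::max(y1, y2) + 1e-9)
    return false;
  return true;
}

// Rasterize a closed polygon: pixel (i, j) (0-based row, col) is foreground
// iff its center (x = j, y = i) lies inside the polygon (even-odd rule) or
// exactly on its boundary. Vertices are given as (x, y) = (col, row).
// [[Rcpp::export(name = ".polygonMask")]]
IntegerMatrix polygonMask(NumericVector xs, NumericVector ys, int nrow,
                          int ncol) {
  const int n = xs.size();
  IntegerMatrix out(nrow, ncol);
  for (int i = 0; i < nrow; ++i) {
    const double py = i;
    for (int j = 0; j < ncol; ++j) {
      const double px = j;
      bool inside = false, boundary = false;
      for (int k = 0; k < n; ++k) {
        const double x1 = xs[k], y1 = ys[k];
        const double x2 = xs[(k + 1) % n], y2 = ys[(k + 1) % n];
        if (on_segment(px, py, x1, y1, x2, y2)) { boundary = true; break; }
        if ((y1 > py) != (y2 > py)) {
          const double xint = x1 + (py - y1) * (x2 - x1) / (y2 - y1);
          if (px < xint) inside = !inside;
        }
      }
      out(i, j) = (inside || boundary) ? 1 : 0;
    }
  }
  return out;
}

// Local maxima of a 3-D volume: voxel must exceed `threshold` and be >= all
// of its (up to 26) in-bounds neighbors. Returns 1-based (row, col, slice)
// indices plus the value.
// [[Rcpp::export(name = ".localMaxima3")]]
NumericMatrix localMaxima3(NumericVector vol, double threshold) {
  IntegerVector dims = vol.attr("dim");
  const int H = dims[0], W = dims[1], S = dims[2];
  arma::cube v(vol.begin(), H, W, S, false);
  std::vector<double> rows, cols, slices, vals;
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double val = v(i, j, s);
        if (val <= threshold) continue;
        bool peak = true;
        for (int ds = -1; ds <= 1 && peak; ++ds)
          for (int dj = -1; dj <= 1 && peak; ++dj)
            for (int di = -1; di <= 1 && peak; ++di) {
              if (di == 0 && dj == 0 && ds == 0) continue;
              const int ii = i + di, jj = j + dj, ss = s + ds;
              if (ii < 0 || ii >= H || jj < 0 || jj >= W || ss < 0 ||
                  ss >= S)
                continue;
              if (v(ii, jj, ss) > val) peak = false;
            }
        if (peak) {
          rows.push_back(i + 1);
          cols.push_back(j + 1);
          slices.push_back(s + 1);
          vals.push_back(val);
        }
      }
  NumericMatrix out(rows.size(), 4);
  for (size_t k = 0; k < rows.size(); ++k) {
    out(k, 0) = rows[k];
    out(k, 1) = cols[k];
    out(k, 2) = slices[k];
    out(k, 3) = vals[k];
  }
  colnames(out) = CharacterVector::create("row", "col", "scale", "value");
  return out;
}
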