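#include <Rcpp.h>
#include <queue>
#include <limits>
#include <cmath>
using namespace Rcpp;

// 8-connected component labeling by breadth-first search.
// Labels are assigned in raster-scan discovery order (1, 2, ...), so the
// component containing the topmost-leftmost foreground pixel is label 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  // row-major scan so labels follow reading order (ties on component size
  // are then resolved by smallest label in R)
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            if (di == 0 && dj == 0) continue;
            int ni = p.first + di, nj = p.second + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope).
static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance from every pixel to the nearest TRUE pixel.
// All-FALSE input yields +Inf everywhere.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix feature) {
  int nr = feature.nrow(), nc = feature.ncol();
  // a large finite sentinel keeps the lower-envelope arithmetic NaN-free;
  // any result that still exceeds it means "no feature pixel anywhere"
  const double BIG = 1e30;
  NumericMatrix d(nr, nc);
  // pass 1: down each column
  for (int j = 0; j < nc; ++j) {
    std::vector<double> col(nr), res(nr);
    for (int i = 0; i < nr; ++i) col[i] = feature(i, j) ? 0.0 : BIG;
    dt1d(col, res);
    for (int i = 0; i < nr; ++i) d(i, j) = res[i];
  }
  // pass 2: along each row
  for (int i = 0; i < nr; ++i) {
    std::vector<double> row(nc), res(nc);
    for (int j = 0; j < nc; ++j) row[j] = d(i, j);
    dt1d(row, res);
    for (int j = 0; j < nc; ++j)
      d(i, j) = (res[j] >= BIG) ? std::numeric_limits<double>::infinity()
                                : res[j];
  }
  return d;
}

// Median filter over a Euclidean disk neighborhood (dx^2 + dy^2 <= r^2),
// truncated at image borders. An even-count neighborhood (borders) takes the
// lower middle value so integer images stay integer.
// [[Rcpp::export]]
NumericMatrix cpp_median_disk(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  if (radius <= 0) return clone(img);
  std::vector<std::pair<int, int> > off;
  for (int di = -radius; di <= radius; ++di)
    for (int dj = -radius; dj <= radius; ++dj)
      if (di * di + dj * dj <= radius * radius) off.push_back(std::make_pair(di, dj));
  NumericMatrix out(nr, nc);
  std::vector<double> vals;
  vals.reserve(off.size());
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      vals.clear();
      for (size_t k = 0; k < off.size(); ++k) {
        int ni = i + off[k].first, nj = j + off[k].second;
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        vals.push_back(img(ni, nj));
      }
      size_t m = (vals.size() - 1) / 2;  // lower middle for even counts
      std::nth_element(vals.begin(), vals.begin() + m, vals.end());
      out(i, j) = vals[m];
    }
  }
  return out;
}

// Outer-boundary perimeter of a single 8-connected component by Moore
// neighbor tracing: edge steps count 1, diagonal steps sqrt(2), in pixel
// units. A single-pixel component has a zero-length chain.
// [[Rcpp::export]]
double cpp_perimeter(LogicalMatrix comp) {
  int nr = comp.nrow(), nc = comp.ncol();
  int si = -1, sj = -1, npix = 0;
  for (int i = 0; i < nr && si < 0; ++i)
    for (int j = 0; j < nc; ++j)
      if (comp(i, j)) { si = i; sj = j; break; }
  if (si < 0) return NA_REAL;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (comp(i, j)) ++npix;
  if (npix == 1) return 0.0;
  // clockwise Moore neighborhood in (row, col) screen coordinates
  const int dr[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int dc[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  const double step[8] = {1.0, M_SQRT2, 1.0, M_SQRT2, 1.0, M_SQRT2, 1.0, M_SQRT2};
  int ci = si, cj = sj;
  int back = 4;  // backtrack points W of the start (background: start is leftmost in its top row)
  double perim = 0.0;
  int first_ni = -1, first_nj = -1;
  long guard = 0, cap = 8L * (long)nr * nc + 16;
  while (guard++ < cap) {
    int found = -1;
    for (int s = 1; s <= 8; ++s) {
      int dir = (back + s) % 8;
      int ni = ci + dr[dir], nj = cj + dc[dir];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (comp(ni, nj)) { found = dir; break; }
    }
    if (found < 0) return 0.0;  // isolated pixel (unreachable for npix > 1 in one component)
    int ni = ci + dr[found], nj = cj + dc[found];
    if (first_ni < 0) { first_ni = ni; first_nj = nj; }
    else if (ci == si && cj == sj && ni == first_ni && nj == first_nj) break;  // Jacob's criterion
    perim += step[found];
    // new backtrack: the last background position scanned before the hit,
    // re-expressed as a direction from the next pixel
    int prev_bg = (found + 7) % 8;
    // direction from next pixel to that background neighbor:
    int bi = ci + dr[prev_bg] - ni, bj = cj + dc[prev_bg] - nj;
    for (int d = 0; d < 8; ++d)
      if (dr[d] == bi && dc[d] == bj) { back = d; break; }
    ci = ni; cj = nj;
  }
  return perim;
}
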