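#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Locate query points inside a triangulation (xy plane).
// Triangles are bucketed on a uniform grid by bounding box so each query
// only tests a handful of candidates; containment is a barycentric test
// with a small relative tolerance so points on shared edges are accepted
// by the first triangle that claims them.
//
// vx, vy: vertex coordinates; tri: M x 3 (1-based vertex indices)
// Returns per query: 1-based triangle index (0 = outside hull) and the
// barycentric coordinates w.r.t. that triangle's three vertices.
// [[Rcpp::export(name = ".locate_points_cpp")]]
List locate_points_cpp(NumericVector vx, NumericVector vy,
                       IntegerMatrix tri,
                       NumericVector qx, NumericVector qy) {
  const int m = tri.nrow(), nq = qx.size();
  IntegerVector out_tri(nq);
  NumericVector b1(nq), b2(nq), b3(nq);
  if (m == 0 || nq == 0) {
    return List::create(_["tri"] = out_tri, _["b1"] = b1, _["b2"] = b2, _["b3"] = b3);
  }
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < vx.size(); ++i) {
    if (vx[i] < xmin) xmin = vx[i];
    if (vx[i] > xmax) xmax = vx[i];
    if (vy[i] < ymin) ymin = vy[i];
    if (vy[i] > ymax) ymax = vy[i];
  }
  double w = std::max(xmax - xmin, 1e-12), h = std::max(ymax - ymin, 1e-12);
  // aim for ~1 triangle per cell
  int nx = std::max(1, (int)std::floor(std::sqrt((double)m * w / h)));
  int ny = std::max(1, (int)std::floor(std::sqrt((double)m * h / w)));
  nx = std::min(nx, 4096); ny = std::min(ny, 4096);
  double cw = w / nx, ch = h / ny;

  std::vector< std::vector<int> > bucket((size_t)nx * ny);
  for (int t = 0; t < m; ++t) {
    int a = tri(t, 0) - 1, b = tri(t, 1) - 1, c = tri(t, 2) - 1;
    double txmin = std::min(vx[a], std::min(vx[b], vx[c]));
    double txmax = std::max(vx[a], std::max(vx[b], vx[c]));
    double tymin = std::min(vy[a], std::min(vy[b], vy[c]));
    double tymax = std::max(vy[a], std::max(vy[b], vy[c]));
    int i0 = std::max(0, std::min(nx - 1, (int)((txmin - xmin) / cw)));
    int i1 = std::max(0, std::min(nx - 1, (int)((txmax - xmin) / cw)));
    int j0 = std::max(0, std::min(ny - 1, (int)((tymin - ymin) / ch)));
    int j1 = std::max(0, std::min(ny - 1, (int)((tymax - ymin) / ch)));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        bucket[(size_t)j * nx + i].push_back(t);
  }

  for (int q = 0; q < nq; ++q) {
    double px = qx[q], py = qy[q];
    out_tri[q] = 0;
    if (px < xmin || px > xmax || py < ymin || py > ymax) continue;
    int ci = std::max(0, std::min(nx - 1, (int)((px - xmin) / cw)));
    int cj = std::max(0, std::min(ny - 1, (int)((py - ymin) / ch)));
    const std::vector<int> &cand = bucket[(size_t)cj * nx + ci];
    for (size_t k = 0; k < cand.size(); ++k) {
      int t = cand[k];
      int a = tri(t, 0) - 1, b = tri(t, 1) - 1, c = tri(t, 2) - 1;
      double x1 = vx[a], y1 = vy[a], x2 = vx[b], y2 = vy[b], x3 = vx[c], y3 = vy[c];
      double det = (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3);
      if (std::fabs(det) < 1e-300) continue;  // degenerate
      double l1 = ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det;
      double l2 = ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det;
      double l3 = 1.0 - l1 - l2;
      double eps = 1e-9;
      if (l1 >= -eps && l2 >= -eps && l3 >= -eps) {
        out_tri[q] = t + 1;
        b1[q] = l1; b2[q] = l2; b3[q] = l3;
        break;
      }
    }
  }
  return List::create(_["tri"] = out_tri, _["b1"] = b1, _["b2"] = b2, _["b3"] = b3);
}

// Variable window filter: local maxima of a raster under a height-adaptive
// circular window of radius r(h) = max(rmin, slope * h) metres.
// A cell is a top iff its value >= min_height and, within its window,
// no other valid cell is larger, and no tied cell precedes it in
// row-major order (row, then column).
// values: rows x cols, NA = nodata. Returns 1-based (row, col) pairs.
// [[Rcpp::export(name = ".vwf_cpp")]]
IntegerMatrix vwf_cpp(NumericMatrix values, double res,
                      double rmin, double slope, double min_height) {
  const int nr = values.nrow(), nc = values.ncol();
  std::vector<int> rows, cols;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double v = values(i, j);
      if (ISNAN(v) || v < min_height) continue;
      double r = std::max(rmin, slope * v);
      int rc = (int)std::floor(r / res);
      double r2 = r * r;
      bool top = true;
      for (int di = -rc; di <= rc && top; ++di) {
        int ii = i + di;
        if (ii < 0 || ii >= nr) continue;
        for (int dj = -rc; dj <= rc; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= nc) continue;
          if (di == 0 && dj == 0) continue;
          double d2 = (double)di * di + (double)dj * dj;
          if (d2 * res * res > r2) continue;
          double u = values(ii, jj);
          if (ISNAN(u)) continue;
          if (u > v || (u == v && (ii < i || (ii == i && jj < j)))) {
            top = false;
            break;
          }
        }
      }
      if (top) { rows.push_back(i + 1); cols.push_back(j + 1); }
    }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t k = 0; k < rows.size(); ++k) {
    out(k, 0) = rows[k];
    out(k, 1) = cols[k];
  }
  return out;
}

// Median filter over valid (non-NA) cells: each valid cell becomes the
// median of the valid cells in its k x k window (self included); nodata
// cells stay nodata. Used to stabilize the CHM before local-maxima search.
// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(NumericMatrix values, int k) {
  const int nr = values.nrow(), nc = values.ncol();
  const int h = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)k * k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = values(i, j);
      if (ISNAN(v)) { out(i, j) = NA_REAL; continue; }
      buf.clear();
      for (int di = -h; di <= h; ++di) {
        int ii = i + di;
        if (ii < 0 || ii >= nr) continue;
        for (int dj = -h; dj <= h; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= nc) continue;
          double u = values(ii, jj);
          if (!ISNAN(u)) buf.push_back(u);
        }
      }
      size_t n = buf.size();
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      double med = buf[n / 2];
      if (n % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + n / 2 - 1, buf.end());
        med = 0.5 * (med + buf[n / 2 - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

struct WsCell {
  double value;
  long order;
  int idx;
  int label;
};
struct WsCmp {
  // process highest value first; FIFO on ties for determinism
  bool operator()(const WsCell &a, const WsCell &b) const {
    if (a.value != b.value) return a.value < b.value;
    return a.order > b.order;
  }
};

// Marker-controlled watershed by priority flooding. Flooding the negated
// surface from the markers is realized by always expanding the highest
// remaining cell, so each basin of -values grows from its marker.
// values: rows x cols (NA = outside mask); markers: same shape, >0 at seeds.
// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerMatrix watershed_cpp(NumericMatrix values, IntegerMatrix markers,
                            bool eight = true) {
  const int nr = values.nrow(), nc = values.ncol();
  IntegerMatrix label(nr, nc);
  std::priority_queue<WsCell, std::vector<WsCell>, WsCmp> pq;
  long counter = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (markers(i, j) > 0 && !ISNAN(values(i, j))) {
        label(i, j) = markers(i, j);
        pq.push(WsCell{values(i, j), counter++, i + j * nr, markers(i, j)});
      }
  const int dio8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int djo8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = eight ? 8 : 4;
  while (!pq.empty()) {
    WsCell c = pq.top();
    pq.pop();
    int i = c.idx % nr, j = c.idx / nr;
    for (int k = 0; k < nnb; ++k) {
      int ii = i + dio8[k], jj = j + djo8[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (label(ii, jj) != 0) continue;
      double v = values(ii, jj);
      if (ISNAN(v)) continue;
      label(ii, jj) = c.label;
      pq.push(WsCell{v, counter++, ii + jj * nr, c.label});
    }
  }
  return label;
}
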