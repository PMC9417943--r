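// Cell-grid accelerated point-to-segment distance queries for the
// capsule-union channel geometry.
#include <Rcpp.h>
using namespace Rcpp;

static inline void segNearest(double px, double py,
                              double x1, double y1, double x2, double y2,
                              double &nx, double &ny, double &d2) {
  const double vx = x2 - x1, vy = y2 - y1;
  const double L2 = vx * vx + vy * vy;
  double t = 0.0;
  if (L2 > 0.0) {
    t = ((px - x1) * vx + (py - y1) * vy) / L2;
    t = t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);
  }
  nx = x1 + t * vx;
  ny = y1 + t * vy;
  const double dx = px - nx, dy = py - ny;
  d2 = dx * dx + dy * dy;
}

// [[Rcpp::export]]
List buildSegmentGridCpp(NumericMatrix segs, double reach,
                         double xmin, double ymin, double cell,
                         int nx, int ny) {
  const int ns = segs.nrow();
  const int ncell = nx * ny;
  std::vector<int> counts(ncell, 0);
  auto cellRange = [&](int j, int &cx0, int &cx1, int &cy0, int &cy1) {
    const double lox = std::min(segs(j, 0), segs(j, 2)) - reach;
    const double hix = std::max(segs(j, 0), segs(j, 2)) + reach;
    const double loy = std::min(segs(j, 1), segs(j, 3)) - reach;
    const double hiy = std::max(segs(j, 1), segs(j, 3)) + reach;
    cx0 = std::max(0, (int)std::floor((lox - xmin) / cell));
    cx1 = std::min(nx - 1, (int)std::floor((hix - xmin) / cell));
    cy0 = std::max(0, (int)std::floor((loy - ymin) / cell));
    cy1 = std::min(ny - 1, (int)std::floor((hiy - ymin) / cell));
  };
  for (int j = 0; j < ns; ++j) {
    int cx0, cx1, cy0, cy1;
    cellRange(j, cx0, cx1, cy0, cy1);
    for (int cx = cx0; cx <= cx1; ++cx)
      for (int cy = cy0; cy <= cy1; ++cy)
        counts[cx + nx * cy]++;
  }
  IntegerVector start(ncell + 1);
  for (int c = 0; c < ncell; ++c) start[c + 1] = start[c] + counts[c];
  IntegerVector index(start[ncell]);
  std::vector<int> fill(ncell, 0);
  for (int j = 0; j < ns; ++j) {
    int cx0, cx1, cy0, cy1;
    cellRange(j, cx0, cx1, cy0, cy1);
    for (int cx = cx0; cx <= cx1; ++cx)
      for (int cy = cy0; cy <= cy1; ++cy) {
        const int c = cx + nx * cy;
        index[start[c] + fill[c]++] = j;   // 0-based segment ids
      }
  }
  return List::create(_["start"] = start, _["index"] = index);
}

// [[Rcpp::export]]
List channelMinDistanceCpp(NumericMatrix points, NumericMatrix segs,
                           double xmin, double ymin, double cell,
                           int nx, int ny,
                           IntegerVector start, IntegerVector index) {
  const int n = points.nrow();
  NumericVector dist(n);
  NumericMatrix nearest(n, 2);
  for (int i = 0; i < n; ++i) {
    const double px = points(i, 0), py = points(i, 1);
    const int cx = (int)std::floor((px - xmin) / cell);
    const int cy = (int)std::floor((py - ymin) / cell);
    double best = R_PosInf, bx = NA_REAL, by = NA_REAL;
    if (cx >= 0 && cx < nx && cy >= 0 && cy < ny) {
      const int c = cx + nx * cy;
      for (int q = start[c]; q < start[c + 1]; ++q) {
        const int j = index[q];
        double qx, qy, d2;
        segNearest(px, py, segs(j, 0), segs(j, 1), segs(j, 2), segs(j, 3),
                   qx, qy, d2);
        if (d2 < best) { best = d2; bx = qx; by = qy; }
      }
    }
    dist[i] = std::isinf(best) ? R_PosInf : std::sqrt(best);
    nearest(i, 0) = bx;
    nearest(i, 1) = by;
  }
  return List::create(_["distance"] = dist, _["nearest"] = nearest);
}
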