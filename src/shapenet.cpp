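#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Coverage rasterizers.  All geometry lives in continuous canvas units with
// the origin at the top-left corner, x rightward (columns), y downward
// (rows).  A pixel grid of nx columns by ny rows spans [0, nx*scale] x
// [0, ny*scale]; `scale` is canvas units per pixel.  Each pixel is sampled
// on an ss x ss subgrid and coverage is the fraction of subsamples inside
// the shape, which gives box-filter antialiasing for ss > 1.

static inline bool point_in_poly(double px, double py,
                                 const std::vector<double>& vx,
                                 const std::vector<double>& vy) {
  // even-odd rule ray cast
  bool inside = false;
  size_t n = vx.size();
  for (size_t i = 0, j = n - 1; i < n; j = i++) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]))
      inside = !inside;
  }
  return inside;
}

static inline double seg_dist2(double px, double py, double x1, double y1,
                               double x2, double y2) {
  double dx = x2 - x1, dy = y2 - y1;
  double L2 = dx * dx + dy * dy;
  double t = 0.0;
  if (L2 > 0) {
    t = ((px - x1) * dx + (py - y1) * dy) / L2;
    t = std::max(0.0, std::min(1.0, t));
  }
  double qx = x1 + t * dx - px, qy = y1 + t * dy - py;
  return qx * qx + qy * qy;
}

struct BBox {
  int i0, i1, j0, j1;  // row/col pixel ranges, 0-based inclusive
};

static BBox pixel_bbox(const std::vector<double>& vx,
                       const std::vector<double>& vy, double pad,
                       double scale, int nx, int ny) {
  double xmin = vx[0], xmax = vx[0], ymin = vy[0], ymax = vy[0];
  for (size_t k = 1; k < vx.size(); ++k) {
    xmin = std::min(xmin, vx[k]); xmax = std::max(xmax, vx[k]);
    ymin = std::min(ymin, vy[k]); ymax = std::max(ymax, vy[k]);
  }
  BBox b;
  b.j0 = std::max(0, (int)std::floor((xmin - pad) / scale) - 1);
  b.j1 = std::min(nx - 1, (int)std::ceil((xmax + pad) / scale) + 1);
  b.i0 = std::max(0, (int)std::floor((ymin - pad) / scale) - 1);
  b.i1 = std::min(ny - 1, (int)std::ceil((ymax + pad) / scale) + 1);
  return b;
}

// [[Rcpp::export(name = ".cov_polygon")]]
NumericMatrix cov_polygon(int nx, int ny, double scale, int ss,
                          NumericVector vxr, NumericVector vyr) {
  std::vector<double> vx(vxr.begin(), vxr.end());
  std::vector<double> vy(vyr.begin(), vyr.end());
  NumericMatrix out(ny, nx);
  BBox b = pixel_bbox(vx, vy, 0.0, scale, nx, ny);
  double inv = 1.0 / (double)(ss * ss);
  for (int i = b.i0; i <= b.i1; ++i) {
    for (int j = b.j0; j <= b.j1; ++j) {
      int hits = 0;
      for (int a = 0; a < ss; ++a) {
        double py = (i + (a + 0.5) / ss) * scale;
        for (int c = 0; c < ss; ++c) {
          double px = (j + (c + 0.5) / ss) * scale;
          if (point_in_poly(px, py, vx, vy)) ++hits;
        }
      }
      if (hits) out(i, j) = hits * inv;
    }
  }
  return out;
}

// Stroked polyline/polygon: coverage where distance to any edge <= halfw.
// closed = true joins the last vertex back to the first.
// [[Rcpp::export(name = ".cov_stroke")]]
NumericMatrix cov_stroke(int nx, int ny, double scale, int ss,
                         NumericVector vxr, NumericVector vyr, double halfw,
                         bool closed) {
  std::vector<double> vx(vxr.begin(), vxr.end());
  std::vector<double> vy(vyr.begin(), vyr.end());
  size_t n = vx.size();
  NumericMatrix out(ny, nx);
  BBox b = pixel_bbox(vx, vy, halfw, scale, nx, ny);
  double hw2 = halfw * halfw;
  double inv = 1.0 / (double)(ss * ss);
  size_t nedge = closed ? n : n - 1;
  for (int i = b.i0; i <= b.i1; ++i) {
    for (int j = b.j0; j <= b.j1; ++j) {
      int hits = 0;
      for (int a = 0; a < ss; ++a) {
        double py = (i + (a + 0.5) / ss) * scale;
        for (int c = 0; c < ss; ++c) {
          double px = (j + (c + 0.5) / ss) * scale;
          for (size_t e = 0; e < nedge; ++e) {
            size_t f = (e + 1) % n;
            if (seg_dist2(px, py, vx[e], vy[e], vx[f], vy[f]) <= hw2) {
              ++hits;
              break;
            }
          }
        }
      }
      if (hits) out(i, j) = hits * inv;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cov_circle")]]
NumericMatrix cov_circle(int nx, int ny, double scale, int ss, double cx,
                         double cy, double r, bool filled, double halfw) {
  NumericMatrix out(ny, nx);
  std::vector<double> vx(2), vy(2);
  vx[0] = cx - r; vx[1] = cx + r; vy[0] = cy - r; vy[1] = cy + r;
  BBox b = pixel_bbox(vx, vy, filled ? 0.0 : halfw, scale, nx, ny);
  double inv = 1.0 / (double)(ss * ss);
  for (int i = b.i0; i <= b.i1; ++i) {
    for (int j = b.j0; j <= b.j1; ++j) {
      int hits = 0;
      for (int a = 0; a < ss; ++a) {
        double py = (i + (a + 0.5) / ss) * scale;
        for (int c = 0; c < ss; ++c) {
          double px = (j + (c + 0.5) / ss) * scale;
          double d = std::sqrt((px - cx) * (px - cx) + (py - cy) * (py - cy));
          bool in = filled ? (d <= r) : (std::fabs(d - r) <= halfw);
          if (in) ++hits;
        }
      }
      if (hits) out(i, j) = hits * inv;
    }
  }
  return out;
}

// Connected-component labeling of a logical mask with 4- or 8-connectivity.
// Labels are 1..k in first-encounter (row-major) order; background is 0.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity) {
  int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * ny);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % ny, cj = idx / ny;
        for (int k = 0; k < nnb; ++k) {
          int ni = ci + di8[k], nj = cj + dj8[k];
          if (ni < 0 || ni >= ny || nj < 0 || nj >= nx) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * ny);
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
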