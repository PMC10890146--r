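// Numeric core for ppmap: bilinear/nearest warping, joint-histogram mutual
// information, area/bilinear resampling, connected components, separable
// Gaussian smoothing, and the regularized displacement-field objective.
//
// Conventions (documented in the package README and used everywhere):
//   * images are R matrices, H rows x W cols;
//   * pixel coordinates are 0-based with x = column, y = row, centers at
//     integer positions;
//   * displacement fields use the backward convention:
//     warped(y, x) = moving(y + v(y,x), x + u(y,x)), samples clamped to the
//     image boundary.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>

using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double sample_bilinear(const NumericMatrix& m, double y, double x) {
  const int H = m.nrow(), W = m.ncol();
  x = clampd(x, 0.0, (double)(W - 1));
  y = clampd(y, 0.0, (double)(H - 1));
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = x0 + 1 < W ? x0 + 1 : x0;
  int y1 = y0 + 1 < H ? y0 + 1 : y0;
  double fx = x - x0, fy = y - y0;
  double a = m(y0, x0), b = m(y0, x1), c = m(y1, x0), d = m(y1, x1);
  return a * (1 - fx) * (1 - fy) + b * fx * (1 - fy) +
         c * (1 - fx) * fy + d * fx * fy;
}

// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(NumericMatrix moving, NumericMatrix u, NumericMatrix v) {
  const int H = moving.nrow(), W = moving.ncol();
  NumericMatrix out(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      out(y, x) = sample_bilinear(moving, y + v(y, x), x + u(y, x));
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_warp_nearest(IntegerMatrix m, NumericMatrix u, NumericMatrix v) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix out(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double sx = clampd(x + u(y, x), 0.0, (double)(W - 1));
      double sy = clampd(y + v(y, x), 0.0, (double)(H - 1));
      out(y, x) = m((int)std::lround(sy), (int)std::lround(sx));
    }
  return out;
}

static inline int bin_index(double val, int bins) {
  double v = clampd(val, 0.0, 1.0);
  int b = (int)(v * bins);
  return b >= bins ? bins - 1 : b;
}

// Mutual information in bits from a hard-binned joint histogram over [0, 1].
// [[Rcpp::export]]
double cpp_mi_bits(NumericMatrix a, NumericMatrix b, int bins) {
  const int H = a.nrow(), W = a.ncol();
  const int n = H * W;
  std::vector<double> joint(bins * bins, 0.0), pa(bins, 0.0), pb(bins, 0.0);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int i = bin_index(a(y, x), bins), j = bin_index(b(y, x), bins);
      joint[i * bins + j] += 1.0;
    }
  for (int i = 0; i < bins; ++i)
    for (int j = 0; j < bins; ++j) {
      joint[i * bins + j] /= n;
      pa[i] += joint[i * bins + j];
      pb[j] += joint[i * bins + j];
    }
  double mi = 0.0;
  const double log2e = 1.0 / std::log(2.0);
  for (int i = 0; i < bins; ++i)
    for (int j = 0; j < bins; ++j) {
      double p = joint[i * bins + j];
      if (p > 0.0) mi += p * std::log(p / (pa[i] * pb[j])) * log2e;
    }
  return mi < 0.0 ? 0.0 : mi;
}

// Bilinear resize with half-pixel center alignment (identity when sizes match).
// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix m, int H, int W) {
  const int H0 = m.nrow(), W0 = m.ncol();
  NumericMatrix out(H, W);
  const double sy = (double)H0 / H, sx = (double)W0 / W;
  for (int y = 0; y < H; ++y) {
    double yy = (y + 0.5) * sy - 0.5;
    for (int x = 0; x < W; ++x) {
      double xx = (x + 0.5) * sx - 0.5;
      out(y, x) = sample_bilinear(m, yy, xx);
    }
  }
  return out;
}

// Exact box-overlap (area-weighted) resampling; mean-preserving for
// downscaling, identity when sizes match.
// [[Rcpp::export]]
NumericMatrix cpp_resize_area(NumericMatrix m, int H, int W) {
  const int H0 = m.nrow(), W0 = m.ncol();
  NumericMatrix out(H, W);
  const double sy = (double)H0 / H, sx = (double)W0 / W;
  for (int y = 0; y < H; ++y) {
    double y0 = y * sy, y1 = (y + 1) * sy;
    int r0 = (int)std::floor(y0), r1 = (int)std::ceil(y1);
    if (r1 > H0) r1 = H0;
    for (int x = 0; x < W; ++x) {
      double x0 = x * sx, x1 = (x + 1) * sx;
      int c0 = (int)std::floor(x0), c1 = (int)std::ceil(x1);
      if (c1 > W0) c1 = W0;
      double acc = 0.0, wsum = 0.0;
      for (int r = r0; r < r1; ++r) {
        double wy = std::min((double)(r + 1), y1) - std::max((double)r, y0);
        for (int c = c0; c < c1; ++c) {
          double wx = std::min((double)(c + 1), x1) - std::max((double)c, x0);
          double w = wy * wx;
          acc += w * m(r, c);
          wsum += w;
        }
      }
      out(y, x) = acc / wsum;
    }
  }
  return out;
}

// 4-connected component labeling of a 0/1 matrix; labels 1..K, background 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> qy, qx;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      if (mask(y, x) == 0 || lab(y, x) != 0) continue;
      ++next;
      qy.clear(); qx.clear();
      qy.push_back(y); qx.push_back(x);
      lab(y, x) = next;
      size_t head = 0;
      while (head < qy.size()) {
        int cy = qy[head], cx = qx[head];
        ++head;
        const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int ny = cy + dy[k], nx = cx + dx[k];
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          if (mask(ny, nx) != 0 && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            qy.push_back(ny); qx.push_back(nx);
          }
        }
      }
    }
  return lab;
}

// Separable Gaussian smoothing, reflected boundaries, radius 3*sigma.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix m, double sigma) {
  const int H = m.nrow(), W = m.ncol();
  if (sigma <= 0.0) return clone(m);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * rad + 1);
  double ks = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    ks += k[i + rad];
  }
  for (double& v : k) v /= ks;
  NumericMatrix tmp(H, W), out(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int c = x + i;
        if (c < 0) c = -c;
        if (c >= W) c = 2 * W - 2 - c;
        if (c < 0) c = 0;            // kernel wider than the image
        if (c >= W) c = W - 1;
        acc += k[i + rad] * m(y, c);
      }
      tmp(y, x) = acc;
    }
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int r = y + i;
        if (r < 0) r = -r;
        if (r >= H) r = 2 * H - 2 - r;
        if (r < 0) r = 0;
        if (r >= H) r = H - 1;
        acc += k[i + rad] * tmp(r, x);
      }
      out(y, x) = acc;
    }
  return out;
}

// Bilinear interpolation of a control-point lattice whose nodes span
// [0, H-1] x [0, W-1] uniformly ("align corners") to a dense H x W field.
// [[Rcpp::export]]
NumericMatrix cpp_grid_to_dense(NumericMatrix g, int H, int W) {
  const int gh = g.nrow(), gw = g.ncol();
  NumericMatrix out(H, W);
  const double sy = gh > 1 ? (double)(gh - 1) / (H - 1) : 0.0;
  const double sx = gw > 1 ? (double)(gw - 1) / (W - 1) : 0.0;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      out(y, x) = sample_bilinear(g, y * sy, x * sx);
  return out;
}

// Regularized registration objective for a control-point displacement grid:
//   MI(fixed, warp(moving, dense(gu, gv))) - lambda * mean squared gradient
// of the dense field (forward differences). Higher is better.
// [[Rcpp::export]]
double cpp_ddf_objective(NumericMatrix fixed, NumericMatrix moving,
                         NumericMatrix gu, NumericMatrix gv,
                         int bins, double lambda) {
  const int H = fixed.nrow(), W = fixed.ncol();
  NumericMatrix u = cpp_grid_to_dense(gu, H, W);
  NumericMatrix v = cpp_grid_to_dense(gv, H, W);
  NumericMatrix warped = cpp_warp_bilinear(moving, u, v);
  double mi = cpp_mi_bits(fixed, warped, bins);
  double pen = 0.0;
  long cnt = 0;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      if (x + 1 < W) {
        double du = u(y, x + 1) - u(y, x), dv = v(y, x + 1) - v(y, x);
        pen += du * du + dv * dv;
        ++cnt;
      }
      if (y + 1 < H) {
        double du = u(y + 1, x) - u(y, x), dv = v(y + 1, x) - v(y, x);
        pen += du * du + dv * dv;
        ++cnt;
      }
    }
  if (cnt > 0) pen /= cnt;
  return mi - lambda * pen;
}
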