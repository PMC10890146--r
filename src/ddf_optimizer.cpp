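// Greedy coordinate-ascent optimizer for one pyramid level of the
// displacement-field estimation. Exploits locality: perturbing one control
// point only changes the dense field inside that node's bilinear support,
// so the joint histogram and the smoothness penalty are updated
// incrementally and each trial move costs O(support area) instead of
// O(image area). The objective matches cpp_ddf_objective:
//   MI(fixed, warp(moving, dense(gu, gv))) - lambda * mean squared gradient.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

inline double sample_bilinear(const NumericMatrix& m, double y, double x) {
  const int H = m.nrow(), W = m.ncol();
  x = clampd(x, 0.0, (double)(W - 1));
  y = clampd(y, 0.0, (double)(H - 1));
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = x0 + 1 < W ? x0 + 1 : x0;
  int y1 = y0 + 1 < H ? y0 + 1 : y0;
  double fx = x - x0, fy = y - y0;
  return m(y0, x0) * (1 - fx) * (1 - fy) + m(y0, x1) * fx * (1 - fy) +
         m(y1, x0) * (1 - fx) * fy + m(y1, x1) * fx * fy;
}

inline int bin_index(double val, int bins) {
  double v = clampd(val, 0.0, 1.0);
  int b = (int)(v * bins);
  return b >= bins ? bins - 1 : b;
}

struct LevelState {
  int H, W, gh, gw, bins;
  double lambda;
  double sy, sx;               // grid coords per pixel
  const NumericMatrix* fixed;
  const NumericMatrix* moving;
  NumericMatrix u, v;          // dense field
  NumericMatrix warped;
  std::vector<int> fbin, wbin; // per-pixel bins (column-major H*W)
  std::vector<double> joint;   // bins x bins counts (exact integers)
  std::vector<double> rsum, csum;
  double pen_sum;              // unnormalized sum of squared differences
  long edge_cnt;
  long npix;

  int idx(int y, int x) const { return x * H + y; }

  void rebuild(const NumericMatrix& gu, const NumericMatrix& gv) {
    u = NumericMatrix(H, W);
    v = NumericMatrix(H, W);
    warped = NumericMatrix(H, W);
    fbin.assign(npix, 0); wbin.assign(npix, 0);
    joint.assign(bins * bins, 0.0);
    rsum.assign(bins, 0.0); csum.assign(bins, 0.0);
    double gsy = gh > 1 ? (double)(gh - 1) / (H - 1) : 0.0;
    double gsx = gw > 1 ? (double)(gw - 1) / (W - 1) : 0.0;
    sy = gsy; sx = gsx;
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        u(y, x) = sample_bilinear(gu, y * gsy, x * gsx);
        v(y, x) = sample_bilinear(gv, y * gsy, x * gsx);
        warped(y, x) = sample_bilinear(*moving, y + v(y, x), x + u(y, x));
        int fb = bin_index((*fixed)(y, x), bins);
        int wb = bin_index(warped(y, x), bins);
        fbin[idx(y, x)] = fb; wbin[idx(y, x)] = wb;
        joint[fb * bins + wb] += 1.0;
        rsum[fb] += 1.0; csum[wb] += 1.0;
      }
    pen_sum = 0.0;
    edge_cnt = 0;
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        if (x + 1 < W) {
          double du = u(y, x + 1) - u(y, x), dv = v(y, x + 1) - v(y, x);
          pen_sum += du * du + dv * dv; ++edge_cnt;
        }
        if (y + 1 < H) {
          double du = u(y + 1, x) - u(y, x), dv = v(y + 1, x) - v(y, x);
          pen_sum += du * du + dv * dv; ++edge_cnt;
        }
      }
  }

  double mi() const {
    double out = 0.0;
    const double N = (double)npix;
    const double log2e = 1.0 / std::log(2.0);
    for (int i = 0; i < bins; ++i) {
      if (rsum[i] == 0.0) continue;
      for (int j = 0; j < bins; ++j) {
        double c = joint[i * bins + j];
        if (c > 0.0)
          out += (c / N) * std::log(c * N / (rsum[i] * csum[j])) * log2e;
      }
    }
    return out < 0.0 ? 0.0 : out;
  }

  double objective() const {
    return mi() - lambda * pen_sum / (double)edge_cnt;
  }

  // Squared-difference sum of the edges whose value can change when pixels
  // in box [y0..y1] x [x0..x1] of one displacement component change.
  double edge_sum(const NumericMatrix& comp, int y0, int y1, int x0, int x1) const {
    double s = 0.0;
    int ex0 = std::max(0, x0 - 1), ex1 = std::min(W - 2, x1);
    for (int y = y0; y <= y1; ++y)
      for (int x = ex0; x <= ex1; ++x) {
        double d = comp(y, x + 1) - comp(y, x);
        s += d * d;
      }
    int ey0 = std::max(0, y0 - 1), ey1 = std::min(H - 2, y1);
    for (int y = ey0; y <= ey1; ++y)
      for (int x = x0; x <= x1; ++x) {
        double d = comp(y + 1, x) - comp(y, x);
        s += d * d;
      }
    return s;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_optimize_level(NumericMatrix fixedimg, NumericMatrix moving,
                        NumericMatrix gu, NumericMatrix gv,
                        int bins, double lambda,
                        NumericVector steps, int max_sweeps) {
  LevelState st;
  st.H = fixedimg.nrow(); st.W = fixedimg.ncol();
  st.gh = gu.nrow(); st.gw = gu.ncol();
  st.bins = bins; st.lambda = lambda;
  st.fixed = &fixedimg; st.moving = &moving;
  st.npix = (long)st.H * st.W;
  st.rebuild(gu, gv);

  std::vector<double> trace;
  double best = st.objective();
  trace.push_back(best);
  bool hit_cap = false;

  // scratch buffers for revert
  std::vector<double> old_comp, old_warp;
  std::vector<int> old_wb;

  const double inv_sy = st.sy > 0 ? 1.0 / st.sy : 0.0;
  const double inv_sx = st.sx > 0 ? 1.0 / st.sx : 0.0;

  for (int si = 0; si < steps.size(); ++si) {
    double step = steps[si];
    int sweep = 0;
    for (;;) {
      ++sweep;
      bool improved = false;
      for (int gi = 0; gi < st.gh; ++gi) {
        for (int gj = 0; gj < st.gw; ++gj) {
          // pixel support of node (gi, gj)
          int y0 = std::max(0, (int)std::ceil((gi - 1) * inv_sy + 1e-12));
          int y1 = std::min(st.H - 1, (int)std::floor((gi + 1) * inv_sy - 1e-12));
          int x0 = std::max(0, (int)std::ceil((gj - 1) * inv_sx + 1e-12));
          int x1 = std::min(st.W - 1, (int)std::floor((gj + 1) * inv_sx - 1e-12));
          if (y1 < y0 || x1 < x0) continue;
          for (int comp = 0; comp < 2; ++comp) {
            NumericMatrix& g = comp == 0 ? gu : gv;
            NumericMatrix& dcomp = comp == 0 ? st.u : st.v;
            for (int dsign = 0; dsign < 2; ++dsign) {
              double delta = dsign == 0 ? step : -step;
              // --- trial move ---
              double pen_old = st.edge_sum(dcomp, y0, y1, x0, x1);
              int nbx = x1 - x0 + 1, nby = y1 - y0 + 1;
              old_comp.assign((size_t)nbx * nby, 0.0);
              old_warp.assign((size_t)nbx * nby, 0.0);
              old_wb.assign((size_t)nbx * nby, 0);
              for (int y = y0; y <= y1; ++y) {
                double wy = 1.0 - std::fabs(y * st.sy - gi);
                for (int x = x0; x <= x1; ++x) {
                  double wx = 1.0 - std::fabs(x * st.sx - gj);
                  double w = wy * wx;
                  size_t b = (size_t)(x - x0) * nby + (y - y0);
                  old_comp[b] = dcomp(y, x);
                  old_warp[b] = st.warped(y, x);
                  old_wb[b] = st.wbin[st.idx(y, x)];
                  dcomp(y, x) += delta * w;
                  double wv = sample_bilinear(moving, y + st.v(y, x), x + st.u(y, x));
                  st.warped(y, x) = wv;
                  int wb = bin_index(wv, bins);
                  int fb = st.fbin[st.idx(y, x)];
                  if (wb != old_wb[b]) {
                    st.joint[fb * bins + old_wb[b]] -= 1.0;
                    st.joint[fb * bins + wb] += 1.0;
                    st.csum[old_wb[b]] -= 1.0;
                    st.csum[wb] += 1.0;
                    st.wbin[st.idx(y, x)] = wb;
                  }
                }
              }
              double pen_new = st.edge_sum(dcomp, y0, y1, x0, x1);
              st.pen_sum += pen_new - pen_old;
              double obj = st.objective();
              if (obj > best + 1e-12) {
                g(gi, gj) += delta;
                best = obj;
                trace.push_back(best);
                improved = true;
                break;   // next component / node
              }
              // --- revert ---
              st.pen_sum -= pen_new - pen_old;
              for (int y = y0; y <= y1; ++y)
                for (int x = x0; x <= x1; ++x) {
                  size_t b = (size_t)(x - x0) * nby + (y - y0);
                  dcomp(y, x) = old_comp[b];
                  int cur = st.wbin[st.idx(y, x)];
                  if (cur != old_wb[b]) {
                    int fb = st.fbin[st.idx(y, x)];
                    st.joint[fb * bins + cur] -= 1.0;
                    st.joint[fb * bins + old_wb[b]] += 1.0;
                    st.csum[cur] -= 1.0;
                    st.csum[old_wb[b]] += 1.0;
                    st.wbin[st.idx(y, x)] = old_wb[b];
                  }
                  st.warped(y, x) = old_warp[b];
                }
            }
          }
        }
      }
      if (!improved) break;
      if (sweep >= max_sweeps) {
        hit_cap = true;
        break;
      }
    }
  }
  return List::create(_["gu"] = gu, _["gv"] = gv,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["hit_cap"] = hit_cap,
                      _["objective"] = best);
}
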