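#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Texture-matrix kernels. All take an integer level image where 0 marks
// pixels outside the ROI mask and 1..ng are discretized gray levels.
// Out-of-mask pixels never pair, break runs, and are not neighbours.

// [[Rcpp::export]]
NumericMatrix cpp_glcm(const IntegerMatrix& levels, int ng, int dr, int dc) {
  int H = levels.nrow(), W = levels.ncol();
  NumericMatrix P(ng, ng);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int a = levels(r, c);
      if (a <= 0) continue;
      int r2 = r + dr, c2 = c + dc;
      if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
      int b = levels(r2, c2);
      if (b <= 0) continue;
      P(a - 1, b - 1) += 1.0;  // symmetric matrix: count both orderings
      P(b - 1, a - 1) += 1.0;
    }
  }
  return P;
}

// [[Rcpp::export]]
NumericMatrix cpp_glrlm(const IntegerMatrix& levels, int ng, int dr, int dc) {
  int H = levels.nrow(), W = levels.ncol();
  int maxlen = std::max(H, W);
  NumericMatrix P(ng, maxlen);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int a = levels(r, c);
      if (a <= 0) continue;
      int rp = r - dr, cp = c - dc;
      bool start = true;
      if (rp >= 0 && rp < H && cp >= 0 && cp < W && levels(rp, cp) == a)
        start = false;  // continuation of a run already counted
      if (!start) continue;
      int len = 0, rr = r, cc = c;
      while (rr >= 0 && rr < H && cc >= 0 && cc < W && levels(rr, cc) == a) {
        ++len; rr += dr; cc += dc;
      }
      P(a - 1, len - 1) += 1.0;
    }
  }
  return P;
}

// 8-connected zones of equal level; returns ng x maxZoneSize counts.
// [[Rcpp::export]]
NumericMatrix cpp_glszm(const IntegerMatrix& levels, int ng) {
  int H = levels.nrow(), W = levels.ncol();
  std::vector<char> seen((size_t)H * W, 0);
  std::vector<std::pair<int, int> > zones;  // (level, size)
  std::vector<int> stack;
  int maxsize = 1;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int a = levels(r, c);
      if (a <= 0 || seen[(size_t)c * H + r]) continue;
      int size = 0;
      stack.clear();
      stack.push_back(c * H + r);
      seen[(size_t)c * H + r] = 1;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % H, cc = idx / H;
        ++size;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
            int j = c2 * H + r2;
            if (!seen[(size_t)j] && levels(r2, c2) == a) {
              seen[(size_t)j] = 1;
              stack.push_back(j);
            }
          }
        }
      }
      zones.push_back(std::make_pair(a, size));
      if (size > maxsize) maxsize = size;
    }
  }
  NumericMatrix P(ng, maxsize);
  for (size_t i = 0; i < zones.size(); ++i)
    P(zones[i].first - 1, zones[i].second - 1) += 1.0;
  return P;
}

// Compact zone list: one row per zone, columns (level, size). Same flood
// fill as cpp_glszm without materializing the ng x maxZoneSize matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(const IntegerMatrix& levels) {
  int H = levels.nrow(), W = levels.ncol();
  std::vector<char> seen((size_t)H * W, 0);
  std::vector<std::pair<int, int> > zones;
  std::vector<int> stack;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int a = levels(r, c);
      if (a <= 0 || seen[(size_t)c * H + r]) continue;
      int size = 0;
      stack.clear();
      stack.push_back(c * H + r);
      seen[(size_t)c * H + r] = 1;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % H, cc = idx / H;
        ++size;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
            int j = c2 * H + r2;
            if (!seen[(size_t)j] && levels(r2, c2) == a) {
              seen[(size_t)j] = 1;
              stack.push_back(j);
            }
          }
        }
      }
      zones.push_back(std::make_pair(a, size));
    }
  }
  IntegerMatrix out(zones.size(), 2);
  for (size_t i = 0; i < zones.size(); ++i) {
    out(i, 0) = zones[i].first;
    out(i, 1) = zones[i].second;
  }
  return out;
}

// Dependence matrix: 8-neighbourhood, |level diff| <= alpha counts as
// dependent; column index = 1 + (# dependent neighbours), so the centre
// pixel is included and the index is always >= 1.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(const IntegerMatrix& levels, int ng, int alpha) {
  int H = levels.nrow(), W = levels.ncol();
  NumericMatrix P(ng, 9);  // dependence in 1..9 for a distance-1 neighbourhood
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int a = levels(r, c);
      if (a <= 0) continue;
      int dep = 0;
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int r2 = r + dr, c2 = c + dc;
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          int b = levels(r2, c2);
          if (b <= 0) continue;
          if (std::abs(a - b) <= alpha) ++dep;
        }
      }
      P(a - 1, dep) += 1.0;  // column dep corresponds to dependence dep+1
    }
  }
  return P;
}

// Per-level counts n_i and summed absolute differences s_i from the mean of
// the valid 8-neighbourhood. Pixels with no valid neighbour are skipped.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(const IntegerMatrix& levels, int ng) {
  int H = levels.nrow(), W = levels.ncol();
  NumericMatrix NS(ng, 2);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int a = levels(r, c);
      if (a <= 0) continue;
      double sum = 0.0; int cnt = 0;
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int r2 = r + dr, c2 = c + dc;
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          int b = levels(r2, c2);
          if (b <= 0) continue;
          sum += b; ++cnt;
        }
      }
      if (cnt == 0) continue;
      NS(a - 1, 0) += 1.0;
      NS(a - 1, 1) += std::fabs((double)a - sum / cnt);
    }
  }
  return NS;
}

static inline int reflect_index(int i, int n) {
  // half-sample symmetric extension: ... x1 x0 | x0 x1 ... xn-1 | xn-1 ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable convolution with centred odd-length kernels, symmetric boundary.
// kr runs along rows (vertical), kc along columns (horizontal).
// [[Rcpp::export]]
NumericMatrix cpp_sepconv2(const NumericMatrix& img,
                           const NumericVector& kr,
                           const NumericVector& kc) {
  int H = img.nrow(), W = img.ncol();
  int Lr = kr.size(), Lc = kc.size();
  int hr = Lr / 2, hc = Lc / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      for (int k = 0; k < Lr; ++k)
        acc += kr[k] * img(reflect_index(r + k - hr, H), c);
      tmp(r, c) = acc;
    }
  }
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      double acc = 0.0;
      for (int k = 0; k < Lc; ++k)
        acc += kc[k] * tmp(r, reflect_index(c + k - hc, W));
      out(r, c) = acc;
    }
  }
  return out;
}

// Full 2D convolution with a small centred kernel, symmetric boundary.
// [[Rcpp::export]]
NumericMatrix cpp_conv2(const NumericMatrix& img, const NumericMatrix& kernel) {
  int H = img.nrow(), W = img.ncol();
  int Kh = kernel.nrow(), Kw = kernel.ncol();
  int hh = Kh / 2, hw = Kw / 2;
  NumericMatrix out(H, W);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      double acc = 0.0;
      for (int i = 0; i < Kh; ++i)
        for (int j = 0; j < Kw; ++j)
          acc += kernel(i, j) * img(reflect_index(r + i - hh, H),
                                    reflect_index(c + j - hw, W));
      out(r, c) = acc;
    }
  }
  return out;
}

// One DWT analysis pass along one axis: symmetric extension by L-1,
// convolution, dyadic decimation. axis 0 = along rows (vertical filtering),
// axis 1 = along columns. Output length floor((n + L - 1) / 2).
// [[Rcpp::export]]
NumericMatrix cpp_dwt_axis(const NumericMatrix& img, const NumericVector& filt,
                           int axis) {
  int H = img.nrow(), W = img.ncol();
  int L = filt.size();
  int n = (axis == 0) ? H : W;
  int m = (n + L - 1) / 2;
  NumericMatrix out(axis == 0 ? m : H, axis == 0 ? W : m);
  int nlanes = (axis == 0) ? W : H;
  for (int lane = 0; lane < nlanes; ++lane) {
    for (int k = 0; k < m; ++k) {
      // full-convolution sample at position 2k + 1; signal coordinates are
      // relative to an implicit symmetric pad of L-1 on the left
      double acc = 0.0;
      int pos = 2 * k + 1;
      for (int j = 0; j < L; ++j) {
        int src = reflect_index(pos - j - (L - 1), n);
        acc += filt[j] * img(axis == 0 ? src : lane, axis == 0 ? lane : src);
      }
      if (axis == 0) out(k, lane) = acc; else out(lane, k) = acc;
    }
  }
  return out;
}
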