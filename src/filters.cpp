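// Sliding-window image filters (mean / median / Shannon entropy of the local
// intensity histogram), Sobel gradient magnitude, resampling, and an even-odd
// scanline polygon rasterizer used by the synthetic vertebra renderer.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Symmetric reflection of an out-of-range index: -1 -> 0, n -> n-1.
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// op: 0 = mean, 1 = median, 2 = entropy (nats, divided by log(base)).
// offsets: m x 2 matrix of (drow, dcol). border: 0 = reflect, 1 = constant.
// [[Rcpp::export]]
NumericMatrix local_filter_cpp(NumericMatrix img, IntegerMatrix offsets, int op,
                               int bins, double lo, double hi, int border,
                               double cval, double logbase) {
  const int H = img.nrow(), W = img.ncol(), m = offsets.nrow();
  NumericMatrix out(H, W);
  std::vector<double> buf(m);
  std::vector<int> hist(bins > 0 ? bins : 1);
  const double binw = (bins > 0 && hi > lo) ? bins / (hi - lo) : 1.0;
  const double lbase = std::log(logbase);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      int n = 0;
      for (int j = 0; j < m; ++j) {
        int hh = h + offsets(j, 0), ww = w + offsets(j, 1);
        double v;
        if (hh < 0 || hh >= H || ww < 0 || ww >= W) {
          if (border == 0) v = img(reflect_idx(hh, H), reflect_idx(ww, W));
          else v = cval;
        } else {
          v = img(hh, ww);
        }
        buf[n++] = v;
      }
      double res;
      if (op == 0) {
        double s = 0;
        for (int j = 0; j < n; ++j) s += buf[j];
        res = s / n;
      } else if (op == 1) {
        std::vector<double> tmp(buf.begin(), buf.begin() + n);
        const int mid = n / 2;
        std::nth_element(tmp.begin(), tmp.begin() + mid, tmp.end());
        if (n % 2 == 1) {
          res = tmp[mid];
        } else {
          double hi2 = tmp[mid];
          std::nth_element(tmp.begin(), tmp.begin() + mid - 1, tmp.end());
          res = 0.5 * (tmp[mid - 1] + hi2);
        }
      } else {
        std::fill(hist.begin(), hist.end(), 0);
        for (int j = 0; j < n; ++j) {
          double v = buf[j];
          if (v < lo) v = lo;
          if (v > hi) v = hi;
          int b = (int)((v - lo) * binw);
          if (b >= bins) b = bins - 1;
          ++hist[b];
        }
        double Hent = 0;
        for (int b = 0; b < bins; ++b) {
          if (hist[b] > 0) {
            const double p = (double)hist[b] / n;
            Hent -= p * std::log(p);
          }
        }
        res = Hent / lbase;
      }
      out(h, w) = res;
    }
  }
  return out;
}

// Sobel gradient magnitude with reflected borders.
// [[Rcpp::export]]
NumericMatrix sobel_cpp(NumericMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      double gx = 0, gy = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const double v = img(reflect_idx(h + di, H), reflect_idx(w + dj, W));
          // x kernel: column weights (-1, 0, 1) times row smoothing (1, 2, 1)
          const int sm_r = (di == 0) ? 2 : 1, sm_c = (dj == 0) ? 2 : 1;
          gx += v * dj * sm_r;
          gy += v * di * sm_c;
        }
      }
      out(h, w) = std::sqrt(gx * gx + gy * gy);
    }
  }
  return out;
}

// Resampling. method: 0 = nearest, 1 = bilinear, 2 = area-weighted average.
// [[Rcpp::export]]
NumericMatrix resize_cpp(NumericMatrix img, int oh, int ow, int method) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(oh, ow);
  const double sy = (double)H / oh, sx = (double)W / ow;
  if (method == 0) {
    for (int j = 0; j < ow; ++j) {
      int js = std::min(W - 1, (int)std::floor((j + 0.5) * sx));
      for (int i = 0; i < oh; ++i) {
        int is = std::min(H - 1, (int)std::floor((i + 0.5) * sy));
        out(i, j) = img(is, js);
      }
    }
  } else if (method == 1) {
    for (int j = 0; j < ow; ++j) {
      double xs = (j + 0.5) * sx - 0.5;
      int x0 = (int)std::floor(xs);
      double fx = xs - x0;
      int x1 = std::min(W - 1, std::max(0, x0 + 1));
      x0 = std::min(W - 1, std::max(0, x0));
      for (int i = 0; i < oh; ++i) {
        double ys = (i + 0.5) * sy - 0.5;
        int y0 = (int)std::floor(ys);
        double fy = ys - y0;
        int y1 = std::min(H - 1, std::max(0, y0 + 1));
        int y0c = std::min(H - 1, std::max(0, y0));
        out(i, j) = (1 - fy) * ((1 - fx) * img(y0c, x0) + fx * img(y0c, x1)) +
                    fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
      }
    }
  } else {
    for (int j = 0; j < ow; ++j) {
      const double xa = j * sx, xb = (j + 1) * sx;
      const int jx0 = (int)std::floor(xa), jx1 = std::min(W, (int)std::ceil(xb));
      for (int i = 0; i < oh; ++i) {
        const double ya = i * sy, yb = (i + 1) * sy;
        const int iy0 = (int)std::floor(ya), iy1 = std::min(H, (int)std::ceil(yb));
        double acc = 0, wsum = 0;
        for (int jj = jx0; jj < jx1; ++jj) {
          const double wx = std::min(xb, (double)jj + 1) - std::max(xa, (double)jj);
          for (int ii = iy0; ii < iy1; ++ii) {
            const double wy = std::min(yb, (double)ii + 1) - std::max(ya, (double)ii);
            acc += wx * wy * img(ii, jj);
            wsum += wx * wy;
          }
        }
        out(i, j) = acc / wsum;
      }
    }
  }
  return out;
}

// Even-odd scanline fill. px are 0-based column coordinates, py 0-based row
// coordinates of a closed polygon (last point joins the first). A pixel is
// filled when its center (integer coordinates) is inside.
// [[Rcpp::export]]
LogicalMatrix fill_polygon_cpp(int nrow, int ncol, NumericVector px, NumericVector py) {
  LogicalMatrix mask(nrow, ncol);
  const int n = px.size();
  std::vector<double> xs;
  for (int r = 0; r < nrow; ++r) {
    const double yc = (double)r;
    xs.clear();
    for (int e = 0; e < n; ++e) {
      const int f = (e + 1) % n;
      const double y1 = py[e], y2 = py[f];
      if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
        xs.push_back(px[e] + (yc - y1) * (px[f] - px[e]) / (y2 - y1));
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int c0 = (int)std::ceil(xs[k]), c1 = (int)std::floor(xs[k + 1]);
      c0 = std::max(0, c0);
      c1 = std::min(ncol - 1, c1);
      for (int c = c0; c <= c1; ++c) mask(r, c) = true;
    }
  }
  return mask;
}
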