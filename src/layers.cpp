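// Neural-network layer kernels: 2-D convolution (same padding, stride 1) via
// batched im2col + GEMM, max pooling, and batch normalization (optionally
// fused with ReLU) over the channel axis. Activations use channels-last
// layout [H, W, C, B] in R's column-major order (H fastest).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Transposed im2col of one image: Mt is (H*W) x (C*k*k); column
// r = c*k*k + kj*k + ki holds the input shifted by (ki - k/2, kj - k/2)
// in (row, col), zero padded. The buffer is reused across the batch.
static void im2col_t(const double* x, int H, int W, int C, int k,
                     arma::mat& Mt) {
  const int half = k / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        double* col = Mt.colptr(r);
        const int dr = ki - half, dc = kj - half;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dc;
          double* dst = col + (size_t)H * w;
          if (ws < 0 || ws >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)H * ws;
          const int h0 = std::max(0, -dr), h1 = std::min(H, H - dr);
          if (h0 > 0) std::fill(dst, dst + h0, 0.0);
          if (h1 > h0) std::copy(src + h0 + dr, src + h1 + dr, dst + h0);
          if (h1 < H) std::fill(dst + std::max(h1, h0), dst + H, 0.0);
        }
      }
    }
  }
}

// x: [H,W,Cin,B]; Wm: (Cin*k*k) x Cout; bias: Cout. Returns [H,W,Cout,B].
// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericMatrix Wm,
                                 NumericVector bias, IntegerVector dims, int k) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int Cout = Wm.ncol();
  const size_t HW = (size_t)H * W;
  NumericVector out(no_init((R_xlen_t)(HW * Cout * B)));
  out.attr("dim") = IntegerVector::create(H, W, Cout, B);
  arma::mat Wa(Wm.begin(), Wm.nrow(), Cout, false, true);
  arma::rowvec ba(bias.begin(), Cout);
  arma::mat Mt(HW, (size_t)C * k * k);
  for (int b = 0; b < B; ++b) {
    im2col_t(x.begin() + HW * C * b, H, W, C, k, Mt);
    arma::mat Y(out.begin() + HW * Cout * b, HW, Cout, false, true);
    Y = Mt * Wa;  // (H*W) x Cout, written directly into the output slab
    Y.each_row() += ba;
  }
  return out;
}

// Gradients of the convolution. dy: [H,W,Cout,B].
// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericMatrix Wm, NumericVector dy,
                         IntegerVector dims, int k) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int Cout = Wm.ncol(), CKK = Wm.nrow(), half = k / 2;
  const size_t HW = (size_t)H * W;
  arma::mat Wa(Wm.begin(), CKK, Cout, false, true);
  NumericVector dx((R_xlen_t)(HW * C * B));  // zero-init: col2im accumulates
  dx.attr("dim") = dims;
  arma::mat dW(CKK, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat Mt(HW, CKK), dMt(HW, CKK);
  for (int b = 0; b < B; ++b) {
    arma::mat dY(const_cast<double*>(dy.begin()) + HW * Cout * b, HW, Cout,
                 false, true);
    im2col_t(x.begin() + HW * C * b, H, W, C, k, Mt);
    dW += Mt.t() * dY;
    db += arma::sum(dY, 0);
    dMt = dY * Wa.t();  // (H*W) x CKK
    double* dxb = dx.begin() + HW * C * b;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxb + HW * c;
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int r = c * k * k + kj * k + ki;
          const double* col = dMt.colptr(r);
          const int dr = ki - half, dc = kj - half;
          for (int w = 0; w < W; ++w) {
            const int wt = w + dc;
            if (wt < 0 || wt >= W) continue;
            double* dst = dxc + (size_t)H * wt;
            const double* src = col + (size_t)H * w;
            const int h0 = std::max(0, -dr), h1 = std::min(H, H - dr);
            for (int h = h0; h < h1; ++h) dst[h + dr] += src[h];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(dW),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Max pooling with window/stride p. Returns pooled values and 0-based argmax
// linear indices into x (for the backward scatter).
// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, IntegerVector dims, int p) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int Ho = H / p, Wo = W / p;
  NumericVector y(no_init((R_xlen_t)Ho * Wo * C * B));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector idx(no_init((R_xlen_t)Ho * Wo * C * B));
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t o = 0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)b * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL;
          size_t bi = 0;
          for (int dw = 0; dw < p; ++dw) {
            const size_t coloff = base + (size_t)H * (wo * p + dw) + ho * p;
            for (int dh = 0; dh < p; ++dh) {
              const double v = xp[coloff + dh];
              if (v > best) { best = v; bi = coloff + dh; }
            }
          }
          yp[o] = best;
          ip[o] = (int)bi;
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector dy, IntegerVector idx,
                                   IntegerVector dims) {
  NumericVector dx((R_xlen_t)dims[0] * dims[1] * dims[2] * dims[3]);
  dx.attr("dim") = dims;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dxp[ip[i]] += dyp[i];
  return dx;
}

// Batch normalization over channels of [H,W,C,B] (dense layers use H=W=1),
// optionally fused with ReLU. Training mode returns the batch mean and
// inverse std needed by the backward pass; inference mode uses the supplied
// running statistics.
// [[Rcpp::export]]
List bn_forward_cpp(NumericVector x, IntegerVector dims, NumericVector gamma,
                    NumericVector beta, NumericVector rmean, NumericVector rvar,
                    double eps, bool training, bool relu) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const size_t HW = (size_t)H * W, stride = HW * C;
  NumericVector y(no_init(x.size()));
  y.attr("dim") = dims;
  NumericVector mu(C), invstd(C);
  const double N = (double)HW * B;
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int b = 0; b < B; ++b) {
        const double* xc = x.begin() + stride * b + HW * c;
        for (size_t i = 0; i < HW; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      }
      m = s / N;
      v = s2 / N - m * m;
      if (v < 0) v = 0;
    } else {
      m = rmean[c];
      v = rvar[c];
    }
    const double is = 1.0 / std::sqrt(v + eps);
    mu[c] = m;
    invstd[c] = is;
    const double g = gamma[c] * is, bt = beta[c] - gamma[c] * is * m;
    for (int b = 0; b < B; ++b) {
      const double* xc = x.begin() + stride * b + HW * c;
      double* yc = y.begin() + stride * b + HW * c;
      if (relu) {
        for (size_t i = 0; i < HW; ++i) {
          const double t = g * xc[i] + bt;
          yc[i] = t > 0 ? t : 0;
        }
      } else {
        for (size_t i = 0; i < HW; ++i) yc[i] = g * xc[i] + bt;
      }
    }
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["invstd"] = invstd);
}

// Backward of (optionally ReLU-fused) batch normalization. When relu is
// true, y must be the forward output; incoming gradients are zeroed where
// the rectifier was inactive (y <= 0).
// [[Rcpp::export]]
List bn_backward_cpp(NumericVector x, NumericVector dy, NumericVector y,
                     IntegerVector dims, NumericVector gamma,
                     NumericVector mean, NumericVector invstd, bool relu) {
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const size_t HW = (size_t)H * W, stride = HW * C;
  NumericVector dx(no_init(x.size()));
  dx.attr("dim") = dims;
  NumericVector dgamma(C), dbeta(C);
  const double N = (double)HW * B;
  for (int c = 0; c < C; ++c) {
    const double m = mean[c], is = invstd[c];
    double sdy = 0.0, sdyx = 0.0;
    for (int b = 0; b < B; ++b) {
      const double* xc = x.begin() + stride * b + HW * c;
      const double* dyc = dy.begin() + stride * b + HW * c;
      const double* yc = relu ? (y.begin() + stride * b + HW * c) : nullptr;
      for (size_t i = 0; i < HW; ++i) {
        const double d = (relu && yc[i] <= 0) ? 0.0 : dyc[i];
        sdy += d;
        sdyx += d * (xc[i] - m) * is;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    const double g = gamma[c] * is;
    const double mdy = sdy / N, mdyx = sdyx / N;
    for (int b = 0; b < B; ++b) {
      const double* xc = x.begin() + stride * b + HW * c;
      const double* dyc = dy.begin() + stride * b + HW * c;
      const double* yc = relu ? (y.begin() + stride * b + HW * c) : nullptr;
      double* dxc = dx.begin() + stride * b + HW * c;
      for (size_t i = 0; i < HW; ++i) {
        const double d = (relu && yc[i] <= 0) ? 0.0 : dyc[i];
        const double xh = (xc[i] - m) * is;
        dxc[i] = g * (d - mdy - xh * mdyx);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// In-place multiply used for dropout masks (avoids an extra allocation).
// [[Rcpp::export]]
NumericVector mul_inplace_cpp(NumericVector x, NumericVector m) {
  double* xp = x.begin();
  const double* mp = m.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) xp[i] *= mp[i];
  return x;
}
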