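// Single-precision training engine for the compact CNN. The network family
// is fixed (conv -> batch norm + ReLU -> max pool -> dropout blocks, then
// dense -> batch norm + ReLU -> dropout -> dense -> softmax); all activation
// and gradient buffers are allocated once per call and reused across
// batches. Randomness (shuffling, dropout) is drawn from R's RNG so results
// are reproducible under set.seed().
#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const float BN_EPS = 1e-5f;
static const float BN_MOM = 0.9f;

struct BlockDims {
  int side;      // input side
  int cin, cout;
  int k, pool;
  double dropout;
  size_t hw() const { return (size_t)side * side; }
  int oside() const { return side / pool; }
};

struct Engine {
  int nb, inputSide, denseWidth, nClasses, Bm;
  double denseDropout;
  std::vector<BlockDims> blk;
  size_t feat;

  // parameters (single precision)
  std::vector<arma::fmat> convW;            // CKK x Cout
  std::vector<arma::fvec> convB, gam, bet, rmean, rvar;
  arma::fmat d1W, d2W;                      // feat x dw, dw x K
  arma::fvec d1b, d2b, gamD, betD, rmeanD, rvarD;

  // activations / caches (sized for Bm)
  std::vector<std::vector<float>> X;        // X[i]: input of block i, i=0..nb
  std::vector<std::vector<float>> Z, A, DM; // conv out, bn+relu out, dropout mask
  std::vector<std::vector<int>> IDX;        // pool argmax
  std::vector<arma::fvec> bnMean, bnInv;    // per block batch stats
  arma::fmat Z1, H1, H1d, DM1, Z2, P;
  arma::fvec bnDMean, bnDInv;

  // gradients
  std::vector<arma::fmat> gConvW;
  std::vector<arma::fvec> gConvB, gGam, gBet;
  arma::fmat gD1W, gD2W;
  arma::fvec gD1b, gD2b, gGamD, gBetD;
  std::vector<std::vector<float>> GX, GZ;   // grad wrt X[i], and a Z-sized scratch
  arma::fmat gZ1, gH1;

  arma::fmat Mt, dMt;                       // im2col scratch (max size)
};

static void buildArch(Engine& E, List arch, int Bm) {
  IntegerVector filters = arch["filters"];
  IntegerVector kernel = arch["kernel"];
  IntegerVector pool = arch["pool"];
  NumericVector dropout = arch["dropout"];
  E.nb = filters.size();
  E.inputSide = as<int>(arch["inputSide"]);
  E.denseWidth = as<int>(arch["denseWidth"]);
  E.denseDropout = as<double>(arch["denseDropout"]);
  E.nClasses = as<int>(arch["nClasses"]);
  E.Bm = Bm;
  int side = E.inputSide, cin = 1;
  size_t mtMax = 0;
  for (int i = 0; i < E.nb; ++i) {
    BlockDims b;
    b.side = side; b.cin = cin; b.cout = filters[i];
    b.k = kernel[i]; b.pool = pool[i]; b.dropout = dropout[i];
    E.blk.push_back(b);
    mtMax = std::max(mtMax, b.hw() * (size_t)(b.cin * b.k * b.k));
    side /= b.pool;
    cin = b.cout;
  }
  E.feat = (size_t)side * side * cin;
  E.Mt.set_size(1, 1); E.Mt.resize(1, 1);
  // buffers
  E.X.resize(E.nb + 1);
  E.Z.resize(E.nb); E.A.resize(E.nb); E.DM.resize(E.nb); E.IDX.resize(E.nb);
  E.GX.resize(E.nb + 1); E.GZ.resize(E.nb);
  E.bnMean.resize(E.nb); E.bnInv.resize(E.nb);
  for (int i = 0; i < E.nb; ++i) {
    const BlockDims& b = E.blk[i];
    E.X[i].resize(b.hw() * b.cin * Bm);
    E.GX[i].resize(b.hw() * b.cin * Bm);
    E.Z[i].resize(b.hw() * b.cout * Bm);
    E.GZ[i].resize(b.hw() * b.cout * Bm);
    E.A[i].resize(b.hw() * b.cout * Bm);
    size_t on = (size_t)b.oside() * b.oside() * b.cout * Bm;
    E.DM[i].resize(on);
    E.IDX[i].resize(on);
    E.bnMean[i].set_size(b.cout); E.bnInv[i].set_size(b.cout);
  }
  E.X[E.nb].resize(E.feat * Bm);
  E.GX[E.nb].resize(E.feat * Bm);
  E.Z1.set_size(E.denseWidth, Bm); E.H1.set_size(E.denseWidth, Bm);
  E.H1d.set_size(E.denseWidth, Bm); E.DM1.set_size(E.denseWidth, Bm);
  E.Z2.set_size(E.nClasses, Bm); E.P.set_size(E.nClasses, Bm);
  E.gZ1.set_size(E.denseWidth, Bm); E.gH1.set_size(E.denseWidth, Bm);
  E.bnDMean.set_size(E.denseWidth); E.bnDInv.set_size(E.denseWidth);
  // largest im2col buffer needed
  size_t ck = 0;
  for (int i = 0; i < E.nb; ++i) {
    ck = std::max(ck, (size_t)(E.blk[i].cin * E.blk[i].k * E.blk[i].k));
  }
  size_t hwmax = 0;
  for (int i = 0; i < E.nb; ++i) hwmax = std::max(hwmax, E.blk[i].hw());
  E.Mt.set_size(hwmax, ck);
  E.dMt.set_size(hwmax, ck);
}

template <typename VecT>
static arma::fvec toF(const VecT& v) {
  arma::fvec out(v.size());
  for (size_t i = 0; i < (size_t)v.size(); ++i) out[i] = (float)v[i];
  return out;
}

static arma::fmat toFM(NumericMatrix m) {
  arma::fmat out(m.nrow(), m.ncol());
  for (size_t i = 0; i < (size_t)m.size(); ++i) out[i] = (float)m[i];
  return out;
}

static void loadParams(Engine& E, List values, List state) {
  for (int i = 0; i < E.nb; ++i) {
    std::string s = std::to_string(i + 1);
    E.convW.push_back(toFM(values["conv" + s + "_W"]));
    E.convB.push_back(toF(as<NumericVector>(values["conv" + s + "_b"])));
    E.gam.push_back(toF(as<NumericVector>(values["bn" + s + "_gamma"])));
    E.bet.push_back(toF(as<NumericVector>(values["bn" + s + "_beta"])));
    E.rmean.push_back(toF(as<NumericVector>(state["bn" + s + "_rmean"])));
    E.rvar.push_back(toF(as<NumericVector>(state["bn" + s + "_rvar"])));
    E.gConvW.push_back(arma::fmat(E.convW[i].n_rows, E.convW[i].n_cols));
    E.gConvB.push_back(arma::fvec(E.convB[i].n_elem));
    E.gGam.push_back(arma::fvec(E.gam[i].n_elem));
    E.gBet.push_back(arma::fvec(E.bet[i].n_elem));
  }
  E.d1W = toFM(values["dense1_W"]);
  E.d1b = toF(as<NumericVector>(values["dense1_b"]));
  E.gamD = toF(as<NumericVector>(values["bnD_gamma"]));
  E.betD = toF(as<NumericVector>(values["bnD_beta"]));
  E.rmeanD = toF(as<NumericVector>(state["bnD_rmean"]));
  E.rvarD = toF(as<NumericVector>(state["bnD_rvar"]));
  E.d2W = toFM(values["dense2_W"]);
  E.d2b = toF(as<NumericVector>(values["dense2_b"]));
  E.gD1W.set_size(E.d1W.n_rows, E.d1W.n_cols);
  E.gD2W.set_size(E.d2W.n_rows, E.d2W.n_cols);
  E.gD1b.set_size(E.d1b.n_elem); E.gD2b.set_size(E.d2b.n_elem);
  E.gGamD.set_size(E.gamD.n_elem); E.gBetD.set_size(E.betD.n_elem);
}

static void im2colF(const float* x, int H, int W, int C, int k, arma::fmat& Mt) {
  const int half = k / 2;
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        float* col = Mt.colptr(r);
        const int dr = ki - half, dc = kj - half;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dc;
          float* dst = col + (size_t)H * w;
          if (ws < 0 || ws >= W) { std::fill(dst, dst + H, 0.0f); continue; }
          const float* src = xc + (size_t)H * ws;
          const int h0 = std::max(0, -dr), h1 = std::min(H, H - dr);
          if (h0 > 0) std::fill(dst, dst + h0, 0.0f);
          if (h1 > h0) std::copy(src + h0 + dr, src + h1 + dr, dst + h0);
          if (h1 < H) std::fill(dst + std::max(h1, h0), dst + H, 0.0f);
        }
      }
    }
  }
}

// Forward through the conv blocks for B images already placed in E.X[0].
// training: batch statistics + dropout (consuming R RNG); else running stats.
static void forwardBlocks(Engine& E, int B, bool training) {
  for (int i = 0; i < E.nb; ++i) {
    const BlockDims& b = E.blk[i];
    const size_t HW = b.hw(), CKK = (size_t)b.cin * b.k * b.k;
    arma::fmat MtV(E.Mt.memptr(), HW, CKK, false, true);
    // conv
    for (int im = 0; im < B; ++im) {
      im2colF(E.X[i].data() + HW * b.cin * im, b.side, b.side, b.cin, b.k, MtV);
      arma::fmat Y(E.Z[i].data() + HW * b.cout * im, HW, b.cout, false, true);
      Y = MtV * E.convW[i];
      Y.each_row() += E.convB[i].t();
    }
    // batch norm (+ ReLU)
    const size_t stride = HW * b.cout;
    const double N = (double)HW * B;
    for (int c = 0; c < b.cout; ++c) {
      float m, v;
      if (training) {
        double s = 0, s2 = 0;
        for (int im = 0; im < B; ++im) {
          const float* zc = E.Z[i].data() + stride * im + HW * c;
          for (size_t q = 0; q < HW; ++q) { s += zc[q]; s2 += zc[q] * zc[q]; }
        }
        m = (float)(s / N);
        double vv = s2 / N - (double)m * m;
        v = (float)(vv < 0 ? 0 : vv);
        const float ub = N > 1 ? (float)(N / (N - 1)) : 1.0f;
        E.rmean[i][c] = BN_MOM * E.rmean[i][c] + (1 - BN_MOM) * m;
        E.rvar[i][c] = BN_MOM * E.rvar[i][c] + (1 - BN_MOM) * v * ub;
      } else {
        m = E.rmean[i][c];
        v = E.rvar[i][c];
      }
      const float is = 1.0f / std::sqrt(v + BN_EPS);
      E.bnMean[i][c] = m; E.bnInv[i][c] = is;
      const float g = E.gam[i][c] * is, bb = E.bet[i][c] - E.gam[i][c] * is * m;
      for (int im = 0; im < B; ++im) {
        const float* zc = E.Z[i].data() + stride * im + HW * c;
        float* ac = E.A[i].data() + stride * im + HW * c;
        for (size_t q = 0; q < HW; ++q) {
          const float t = g * zc[q] + bb;
          ac[q] = t > 0 ? t : 0;
        }
      }
    }
    // max pool + dropout; output into X[i+1]
    const int os = b.oside(), p = b.pool;
    const size_t OHW = (size_t)os * os;
    float* out = E.X[i + 1].data();
    const bool drop = training && b.dropout > 0;
    const float inv = drop ? 1.0f / (1.0f - (float)b.dropout) : 1.0f;
    for (int im = 0; im < B; ++im) {
      for (int c = 0; c < b.cout; ++c) {
        const size_t base = ((size_t)im * b.cout + c) * HW;
        size_t o = ((size_t)im * b.cout + c) * OHW;
        for (int wo = 0; wo < os; ++wo) {
          for (int ho = 0; ho < os; ++ho) {
            float best = -HUGE_VALF;
            size_t bi = 0;
            for (int dw = 0; dw < p; ++dw) {
              const size_t off = base + (size_t)b.side * (wo * p + dw) + ho * p;
              for (int dh = 0; dh < p; ++dh) {
                const float vv = E.A[i][off + dh];
                if (vv > best) { best = vv; bi = off + dh; }
              }
            }
            E.IDX[i][o] = (int)bi;
            if (drop) {
              const float mk = (unif_rand() >= b.dropout) ? inv : 0.0f;
              E.DM[i][o] = mk;
              out[o] = best * mk;
            } else {
              out[o] = best;
            }
            ++o;
          }
        }
      }
    }
  }
}

// Dense head forward. Returns mean batch loss; fills E.P.
static double forwardHead(Engine& E, int B, bool training, const int* y) {
  arma::fmat F(E.X[E.nb].data(), E.feat, B, false, true);
  arma::fmat Z1v(E.Z1.memptr(), E.denseWidth, B, false, true);
  Z1v = E.d1W.t() * F;
  Z1v.each_col() += E.d1b;
  const int dw = E.denseWidth;
  const double N = B;
  for (int c = 0; c < dw; ++c) {
    float m, v;
    if (training) {
      double s = 0, s2 = 0;
      for (int im = 0; im < B; ++im) {
        const float z = E.Z1(c, im);
        s += z; s2 += (double)z * z;
      }
      m = (float)(s / N);
      double vv = s2 / N - (double)m * m;
      v = (float)(vv < 0 ? 0 : vv);
      const float ub = N > 1 ? (float)(N / (N - 1)) : 1.0f;
      E.rmeanD[c] = BN_MOM * E.rmeanD[c] + (1 - BN_MOM) * m;
      E.rvarD[c] = BN_MOM * E.rvarD[c] + (1 - BN_MOM) * v * ub;
    } else {
      m = E.rmeanD[c]; v = E.rvarD[c];
    }
    const float is = 1.0f / std::sqrt(v + BN_EPS);
    E.bnDMean[c] = m; E.bnDInv[c] = is;
    const float g = E.gamD[c] * is, bb = E.betD[c] - E.gamD[c] * is * m;
    for (int im = 0; im < B; ++im) {
      const float t = g * E.Z1(c, im) + bb;
      E.H1(c, im) = t > 0 ? t : 0;
    }
  }
  const bool drop = training && E.denseDropout > 0;
  if (drop) {
    const float inv = 1.0f / (1.0f - (float)E.denseDropout);
    for (int im = 0; im < B; ++im) {
      for (int c = 0; c < dw; ++c) {
        const float mk = (unif_rand() >= E.denseDropout) ? inv : 0.0f;
        E.DM1(c, im) = mk;
        E.H1d(c, im) = E.H1(c, im) * mk;
      }
    }
  } else {
    E.H1d.cols(0, B - 1) = E.H1.cols(0, B - 1);
  }
  arma::fmat H1v(E.H1d.memptr(), dw, B, false, true);
  arma::fmat Z2v(E.Z2.memptr(), E.nClasses, B, false, true);
  Z2v = E.d2W.t() * H1v;
  Z2v.each_col() += E.d2b;
  double loss = 0;
  for (int im = 0; im < B; ++im) {
    float mx = E.Z2(0, im);
    for (int j = 1; j < E.nClasses; ++j) mx = std::max(mx, E.Z2(j, im));
    double se = 0;
    for (int j = 0; j < E.nClasses; ++j) {
      const double e = std::exp((double)E.Z2(j, im) - mx);
      E.P(j, im) = (float)e;
      se += e;
    }
    for (int j = 0; j < E.nClasses; ++j) E.P(j, im) /= (float)se;
    if (y) {
      double pt = E.P(y[im] - 1, im);
      if (pt < 1e-12) pt = 1e-12;
      loss -= std::log(pt);
    }
  }
  return loss / B;
}

// Backward pass; fills all gradient members. y is 1-based.
static void backward(Engine& E, int B, const int* y) {
  const int K = E.nClasses, dw = E.denseWidth;
  arma::fmat dZ2(K, B);
  for (int im = 0; im < B; ++im) {
    for (int j = 0; j < K; ++j) dZ2(j, im) = E.P(j, im);
    dZ2(y[im] - 1, im) -= 1.0f;
  }
  dZ2 /= (float)B;
  arma::fmat H1v(E.H1d.memptr(), dw, B, false, true);
  E.gD2W = H1v * dZ2.t();
  E.gD2b = arma::sum(dZ2, 1);
  arma::fmat dH(E.gH1.memptr(), dw, B, false, true);
  dH = E.d2W * dZ2;
  if (E.denseDropout > 0) {
    // masks only exist when training with dropout; backward always follows
    // a training forward
    for (int im = 0; im < B; ++im) {
      for (int c = 0; c < dw; ++c) dH(c, im) *= E.DM1(c, im);
    }
  }
  // dense BN (+ReLU) backward
  arma::fmat dZ1(E.gZ1.memptr(), dw, B, false, true);
  const double N = B;
  for (int c = 0; c < dw; ++c) {
    const float m = E.bnDMean[c], is = E.bnDInv[c];
    double sdy = 0, sdyx = 0;
    for (int im = 0; im < B; ++im) {
      const float d = E.H1(c, im) > 0 ? dH(c, im) : 0.0f;
      sdy += d;
      sdyx += (double)d * (E.Z1(c, im) - m) * is;
    }
    E.gGamD[c] = (float)sdyx;
    E.gBetD[c] = (float)sdy;
    const float g = E.gamD[c] * is;
    const float mdy = (float)(sdy / N), mdyx = (float)(sdyx / N);
    for (int im = 0; im < B; ++im) {
      const float d = E.H1(c, im) > 0 ? dH(c, im) : 0.0f;
      const float xh = (E.Z1(c, im) - m) * is;
      dZ1(c, im) = g * (d - mdy - xh * mdyx);
    }
  }
  arma::fmat F(E.X[E.nb].data(), E.feat, B, false, true);
  E.gD1W = F * dZ1.t();
  E.gD1b = arma::sum(dZ1, 1);
  arma::fmat dF(E.GX[E.nb].data(), E.feat, B, false, true);
  dF = E.d1W * dZ1;

  for (int i = E.nb - 1; i >= 0; --i) {
    const BlockDims& b = E.blk[i];
    const size_t HW = b.hw(), CKK = (size_t)b.cin * b.k * b.k;
    const int os = b.oside();
    const size_t OHW = (size_t)os * os;
    const size_t on = OHW * b.cout * B;
    float* gpool = E.GX[i + 1].data();
    if (b.dropout > 0) {
      for (size_t q = 0; q < on; ++q) gpool[q] *= E.DM[i][q];
    }
    // pool backward into GZ (Z-sized scratch, zeroed)
    std::fill(E.GZ[i].begin(), E.GZ[i].begin() + HW * b.cout * B, 0.0f);
    for (size_t q = 0; q < on; ++q) E.GZ[i][E.IDX[i][q]] += gpool[q];
    // BN (+ReLU) backward, in place over GZ
    const size_t stride = HW * b.cout;
    const double NN = (double)HW * B;
    for (int c = 0; c < b.cout; ++c) {
      const float m = E.bnMean[i][c], is = E.bnInv[i][c];
      double sdy = 0, sdyx = 0;
      for (int im = 0; im < B; ++im) {
        const float* zc = E.Z[i].data() + stride * im + HW * c;
        const float* ac = E.A[i].data() + stride * im + HW * c;
        float* dc = E.GZ[i].data() + stride * im + HW * c;
        for (size_t q = 0; q < HW; ++q) {
          const float d = ac[q] > 0 ? dc[q] : 0.0f;
          dc[q] = d;  // store the rectified gradient back
          sdy += d;
          sdyx += (double)d * (zc[q] - m) * is;
        }
      }
      E.gGam[i][c] = (float)sdyx;
      E.gBet[i][c] = (float)sdy;
      const float g = E.gam[i][c] * is;
      const float mdy = (float)(sdy / NN), mdyx = (float)(sdyx / NN);
      for (int im = 0; im < B; ++im) {
        const float* zc = E.Z[i].data() + stride * im + HW * c;
        float* dc = E.GZ[i].data() + stride * im + HW * c;
        for (size_t q = 0; q < HW; ++q) {
          const float xh = (zc[q] - m) * is;
          dc[q] = g * (dc[q] - mdy - xh * mdyx);
        }
      }
    }
    // conv backward
    E.gConvW[i].zeros();
    E.gConvB[i].zeros();
    std::fill(E.GX[i].begin(), E.GX[i].begin() + HW * b.cin * B, 0.0f);
    arma::fmat MtV(E.Mt.memptr(), HW, CKK, false, true);
    arma::fmat dMtV(E.dMt.memptr(), HW, CKK, false, true);
    const int half = b.k / 2;
    for (int im = 0; im < B; ++im) {
      arma::fmat dY(E.GZ[i].data() + stride * im, HW, b.cout, false, true);
      im2colF(E.X[i].data() + HW * b.cin * im, b.side, b.side, b.cin, b.k, MtV);
      E.gConvW[i] += MtV.t() * dY;
      E.gConvB[i] += arma::sum(dY, 0).t();
      dMtV = dY * E.convW[i].t();
      float* dxb = E.GX[i].data() + HW * b.cin * im;
      for (int c = 0; c < b.cin; ++c) {
        float* dxc = dxb + HW * c;
        for (int kj = 0; kj < b.k; ++kj) {
          for (int ki = 0; ki < b.k; ++ki) {
            const int r = c * b.k * b.k + kj * b.k + ki;
            const float* col = dMtV.colptr(r);
            const int dr = ki - half, dc = kj - half;
            for (int w = 0; w < b.side; ++w) {
              const int wt = w + dc;
              if (wt < 0 || wt >= b.side) continue;
              float* dst = dxc + (size_t)b.side * wt;
              const float* src = col + (size_t)b.side * w;
              const int h0 = std::max(0, -dr), h1 = std::min(b.side, b.side - dr);
              for (int h = h0; h < h1; ++h) dst[h + dr] += src[h];
            }
          }
        }
      }
    }
  }
}

struct Optim {
  int type;  // 0 sgd, 1 adam
  float lr, momentum, beta1, beta2;
  long t = 0;
  std::vector<arma::fmat> mW, vW;
  std::vector<arma::fvec> mV, vV;
};

// parameter/gradient enumeration helpers
static void forEachParam(Engine& E,
                         const std::function<void(arma::fmat&, arma::fmat&)>& fm,
                         const std::function<void(arma::fvec&, arma::fvec&)>& fv) {
  for (int i = 0; i < E.nb; ++i) {
    fm(E.convW[i], E.gConvW[i]);
    fv(E.convB[i], E.gConvB[i]);
    fv(E.gam[i], E.gGam[i]);
    fv(E.bet[i], E.gBet[i]);
  }
  fm(E.d1W, E.gD1W); fv(E.d1b, E.gD1b);
  fv(E.gamD, E.gGamD); fv(E.betD, E.gBetD);
  fm(E.d2W, E.gD2W); fv(E.d2b, E.gD2b);
}

static void optimInit(Engine& E, Optim& O) {
  forEachParam(E,
    [&](arma::fmat& p, arma::fmat&) {
      O.mW.push_back(arma::fmat(p.n_rows, p.n_cols, arma::fill::zeros));
      O.vW.push_back(arma::fmat(p.n_rows, p.n_cols, arma::fill::zeros));
    },
    [&](arma::fvec& p, arma::fvec&) {
      O.mV.push_back(arma::fvec(p.n_elem, arma::fill::zeros));
      O.vV.push_back(arma::fvec(p.n_elem, arma::fill::zeros));
    });
}

static void optimStep(Engine& E, Optim& O) {
  size_t im = 0, iv = 0;
  if (O.type == 0) {
    forEachParam(E,
      [&](arma::fmat& p, arma::fmat& g) {
        O.mW[im] = O.momentum * O.mW[im] - O.lr * g;
        p += O.mW[im]; ++im;
      },
      [&](arma::fvec& p, arma::fvec& g) {
        O.mV[iv] = O.momentum * O.mV[iv] - O.lr * g;
        p += O.mV[iv]; ++iv;
      });
  } else {
    O.t += 1;
    const float c1 = 1 - std::pow(O.beta1, (float)O.t);
    const float c2 = 1 - std::pow(O.beta2, (float)O.t);
    forEachParam(E,
      [&](arma::fmat& p, arma::fmat& g) {
        O.mW[im] = O.beta1 * O.mW[im] + (1 - O.beta1) * g;
        O.vW[im] = O.beta2 * O.vW[im] + (1 - O.beta2) * (g % g);
        p -= O.lr * (O.mW[im] / c1) / (arma::sqrt(O.vW[im] / c2) + 1e-8f);
        ++im;
      },
      [&](arma::fvec& p, arma::fvec& g) {
        O.mV[iv] = O.beta1 * O.mV[iv] + (1 - O.beta1) * g;
        O.vV[iv] = O.beta2 * O.vV[iv] + (1 - O.beta2) * (g % g);
        p -= O.lr * (O.mV[iv] / c1) / (arma::sqrt(O.vV[iv] / c2) + 1e-8f);
        ++iv;
      });
  }
}

// copy B images (double, [H,W,N] with 1 channel) into E.X[0] as float
static void loadBatch(Engine& E, const double* x, size_t hw, const int* idx,
                      int B) {
  for (int im = 0; im < B; ++im) {
    const double* src = x + hw * (size_t)(idx[im] - 1);
    float* dst = E.X[0].data() + hw * im;
    for (size_t q = 0; q < hw; ++q) dst[q] = (float)src[q];
  }
}

static List dumpParams(Engine& E, CharacterVector namesV, List values,
                       List state) {
  List outV = clone(values), outS = clone(state);
  for (int i = 0; i < E.nb; ++i) {
    std::string s = std::to_string(i + 1);
    NumericMatrix w(E.convW[i].n_rows, E.convW[i].n_cols);
    for (size_t q = 0; q < (size_t)w.size(); ++q) w[q] = E.convW[i][q];
    outV["conv" + s + "_W"] = w;
    outV["conv" + s + "_b"] = NumericVector(E.convB[i].begin(), E.convB[i].end());
    outV["bn" + s + "_gamma"] = NumericVector(E.gam[i].begin(), E.gam[i].end());
    outV["bn" + s + "_beta"] = NumericVector(E.bet[i].begin(), E.bet[i].end());
    outS["bn" + s + "_rmean"] = NumericVector(E.rmean[i].begin(), E.rmean[i].end());
    outS["bn" + s + "_rvar"] = NumericVector(E.rvar[i].begin(), E.rvar[i].end());
  }
  NumericMatrix w1(E.d1W.n_rows, E.d1W.n_cols);
  for (size_t q = 0; q < (size_t)w1.size(); ++q) w1[q] = E.d1W[q];
  outV["dense1_W"] = w1;
  outV["dense1_b"] = NumericVector(E.d1b.begin(), E.d1b.end());
  outV["bnD_gamma"] = NumericVector(E.gamD.begin(), E.gamD.end());
  outV["bnD_beta"] = NumericVector(E.betD.begin(), E.betD.end());
  outS["bnD_rmean"] = NumericVector(E.rmeanD.begin(), E.rmeanD.end());
  outS["bnD_rvar"] = NumericVector(E.rvarD.begin(), E.rvarD.end());
  NumericMatrix w2(E.d2W.n_rows, E.d2W.n_cols);
  for (size_t q = 0; q < (size_t)w2.size(); ++q) w2[q] = E.d2W[q];
  outV["dense2_W"] = w2;
  outV["dense2_b"] = NumericVector(E.d2b.begin(), E.d2b.end());
  return List::create(_["values"] = outV, _["state"] = outS);
}

// Evaluation-mode loss/accuracy over a dataset.
static void evalSet(Engine& E, const double* x, const int* y, int n,
                    double* lossOut, double* accOut) {
  const size_t hw = (size_t)E.inputSide * E.inputSide;
  double loss = 0;
  int correct = 0;
  std::vector<int> idx(E.Bm);
  for (int s = 0; s < n; s += E.Bm) {
    const int B = std::min(E.Bm, n - s);
    for (int i = 0; i < B; ++i) idx[i] = s + i + 1;
    loadBatch(E, x, hw, idx.data(), B);
    forwardBlocks(E, B, false);
    forwardHead(E, B, false, nullptr);
    for (int im = 0; im < B; ++im) {
      int am = 0;
      for (int j = 1; j < E.nClasses; ++j) if (E.P(j, im) > E.P(am, im)) am = j;
      if (am == y[s + im] - 1) ++correct;
      double pt = E.P(y[s + im] - 1, im);
      if (pt < 1e-12) pt = 1e-12;
      loss -= std::log(pt);
    }
  }
  *lossOut = loss / n;
  *accOut = (double)correct / n;
}

// [[Rcpp::export]]
List cvm_train_cpp(NumericVector x, IntegerVector y, Nullable<NumericVector> valx,
                   Nullable<IntegerVector> valy, List values, List state,
                   List arch, List opt, int epochs, int batchSize,
                   bool shuffle, Nullable<NumericVector> lrSchedule,
                   bool keepBest) {
  const int n = y.size();
  const int Bm = std::min(batchSize, n);
  Engine E;
  buildArch(E, arch, Bm);
  loadParams(E, values, state);
  Optim O;
  O.type = as<std::string>(opt["optimizer"]) == "sgd" ? 0 : 1;
  O.lr = (float)as<double>(opt["learningRate"]);
  O.momentum = (float)as<double>(opt["momentum"]);
  O.beta1 = (float)as<double>(opt["beta1"]);
  O.beta2 = (float)as<double>(opt["beta2"]);
  optimInit(E, O);

  const size_t hw = (size_t)E.inputSide * E.inputSide;
  GetRNGstate();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i + 1;

  NumericVector schedule;
  const bool lrMode = lrSchedule.isNotNull();
  if (lrMode) schedule = lrSchedule.get();
  const int nSteps = lrMode ? schedule.size() : 0;
  std::vector<double> stepLosses(lrMode ? nSteps : 0);

  const int nEpochs = lrMode ? 1 : epochs;
  NumericVector trLoss(nEpochs, NA_REAL), trAcc(nEpochs, NA_REAL);
  NumericVector vlLoss(nEpochs, NA_REAL), vlAcc(nEpochs, NA_REAL);
  bool abortNa = false;
  int naEpoch = 0, naBatch = 0;
  List best = R_NilValue;
  double bestAcc = -1;
  int bestEpoch = 0;

  if (lrMode) {
    int pos = 0;
    for (int k = 0; k < nSteps && !abortNa; ++k) {
      std::vector<int> idx(Bm);
      for (int i = 0; i < Bm; ++i) idx[i] = ((pos + i) % n) + 1;
      pos = (pos + batchSize) % n;
      loadBatch(E, x.begin(), hw, idx.data(), Bm);
      std::vector<int> yb(Bm);
      for (int i = 0; i < Bm; ++i) yb[i] = y[idx[i] - 1];
      forwardBlocks(E, Bm, true);
      const double loss = forwardHead(E, Bm, true, yb.data());
      stepLosses[k] = loss;
      if (!std::isfinite(loss)) { abortNa = true; naEpoch = 1; naBatch = k + 1; break; }
      backward(E, Bm, yb.data());
      O.lr = (float)schedule[k];
      optimStep(E, O);
    }
  } else {
    for (int ep = 0; ep < nEpochs && !abortNa; ++ep) {
      if (shuffle) {
        for (int i = n - 1; i > 0; --i) {
          const int j = (int)(unif_rand() * (i + 1));
          std::swap(ord[i], ord[j]);
        }
      }
      double epLoss = 0;
      int epCorrect = 0;
      int bi = 0;
      for (int s = 0; s < n; s += batchSize, ++bi) {
        const int B = std::min(batchSize, n - s);
        loadBatch(E, x.begin(), hw, ord.data() + s, B);
        std::vector<int> yb(B);
        for (int i = 0; i < B; ++i) yb[i] = y[ord[s + i] - 1];
        forwardBlocks(E, B, true);
        const double loss = forwardHead(E, B, true, yb.data());
        if (!std::isfinite(loss)) {
          abortNa = true; naEpoch = ep + 1; naBatch = bi + 1; break;
        }
        epLoss += loss * B;
        for (int im = 0; im < B; ++im) {
          int am = 0;
          for (int j = 1; j < E.nClasses; ++j) {
            if (E.P(j, im) > E.P(am, im)) am = j;
          }
          if (am == yb[im] - 1) ++epCorrect;
        }
        backward(E, B, yb.data());
        optimStep(E, O);
      }
      if (abortNa) break;
      trLoss[ep] = epLoss / n;
      trAcc[ep] = (double)epCorrect / n;
      if (valx.isNotNull()) {
        NumericVector vx = valx.get();
        IntegerVector vy = valy.get();
        double vl, va;
        evalSet(E, vx.begin(), vy.begin(), vy.size(), &vl, &va);
        vlLoss[ep] = vl;
        vlAcc[ep] = va;
        if (keepBest && va > bestAcc) {
          bestAcc = va;
          bestEpoch = ep + 1;
          best = dumpParams(E, values.names(), values, state);
        }
      }
    }
  }
  PutRNGstate();
  List params = dumpParams(E, values.names(), values, state);
  return List::create(
    _["values"] = params["values"], _["state"] = params["state"],
    _["train_loss"] = trLoss, _["train_accuracy"] = trAcc,
    _["val_loss"] = vlLoss, _["val_accuracy"] = vlAcc,
    _["stepLosses"] = wrap(stepLosses),
    _["abort"] = abortNa, _["naEpoch"] = naEpoch, _["naBatch"] = naBatch,
    _["best"] = best, _["bestEpoch"] = bestEpoch, _["bestAcc"] = bestAcc
  );
}

// [[Rcpp::export]]
NumericMatrix cvm_predict_cpp(NumericVector x, int n, List values, List state,
                              List arch, int batchSize) {
  Engine E;
  buildArch(E, arch, std::min(batchSize, std::max(1, n)));
  loadParams(E, values, state);
  const size_t hw = (size_t)E.inputSide * E.inputSide;
  NumericMatrix out(n, E.nClasses);
  std::vector<int> idx(E.Bm);
  for (int s = 0; s < n; s += E.Bm) {
    const int B = std::min(E.Bm, n - s);
    for (int i = 0; i < B; ++i) idx[i] = s + i + 1;
    loadBatch(E, x.begin(), hw, idx.data(), B);
    forwardBlocks(E, B, false);
    forwardHead(E, B, false, nullptr);
    for (int im = 0; im < B; ++im) {
      for (int j = 0; j < E.nClasses; ++j) out(s + im, j) = E.P(j, im);
    }
  }
  return out;
}
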