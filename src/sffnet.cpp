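// Single-precision CNN engine for the strided feature fusion residual
// network (SFFNet): conv2d via im2col + BLAS gemm, fused batch-norm/ReLU,
// 3x3/2 max-pooling, CBAM channel+spatial attention, pre-activation SRB
// bottleneck blocks, and a multilayer-fusion head that global-average-pools
// the concatenation of stem, shallow-stage and deep-stage feature maps
// (the two deeper maps entering through exact bilinear-upsampling weights,
// so the fused map never has to be materialized during training).
// Everything is deterministic for a fixed seed on fixed hardware.

#include <RcppArmadillo.h>
#include <random>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::frowvec;
using arma::fcube;

// ---------------------------------------------------------------------------
// batch tensor: cube of (H*W, C, B); pixel index p = h*W + w (row-major)
struct Ten {
  int B = 0, C = 0, H = 0, W = 0;
  fcube d;
  void init(int B_, int C_, int H_, int W_, bool zero = true) {
    B = B_; C = C_; H = H_; W = W_;
    d.set_size((arma::uword)H * W, C, B);
    if (zero) d.zeros();
  }
  size_t HW() const { return (size_t)H * W; }
};

static Ten r_to_ten(const NumericVector& x) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-D array (H, W, C, B)");
  int H = dm[0], W = dm[1], C = dm[2], B = dm[3];
  Ten t; t.init(B, C, H, W, false);
  const double* px = x.begin();
  for (int b = 0; b < B; b++)
    for (int c = 0; c < C; c++) {
      const double* base = px + (size_t)H * W * (c + (size_t)C * b);
      float* dst = t.d.slice(b).colptr(c);
      for (int w = 0; w < W; w++)
        for (int h = 0; h < H; h++)
          dst[(size_t)h * W + w] = (float)base[h + (size_t)H * w];
    }
  return t;
}

static NumericVector ten_to_r(const Ten& t) {
  NumericVector out((R_xlen_t)t.H * t.W * t.C * t.B);
  out.attr("dim") = IntegerVector::create(t.H, t.W, t.C, t.B);
  double* po = out.begin();
  for (int b = 0; b < t.B; b++)
    for (int c = 0; c < t.C; c++) {
      double* base = po + (size_t)t.H * t.W * (c + (size_t)t.C * b);
      const float* src = t.d.slice(b).colptr(c);
      for (int w = 0; w < t.W; w++)
        for (int h = 0; h < t.H; h++)
          base[h + (size_t)t.H * w] = (double)src[(size_t)h * t.W + w];
    }
  return out;
}

// ---------------------------------------------------------------------------
// im2col / col2im (zero padding)
static void im2col(const fmat& X, int C, int H, int W, int k, int stride,
                   int pad, int oH, int oW, fmat& col) {
  col.set_size((arma::uword)oH * oW, (arma::uword)C * k * k);
  for (int c = 0; c < C; c++) {
    const float* xc = X.colptr(c);
    for (int ki = 0; ki < k; ki++)
      for (int kj = 0; kj < k; kj++) {
        float* cc = col.colptr((size_t)c * k * k + (size_t)ki * k + kj);
        for (int oh = 0; oh < oH; oh++) {
          int ih = oh * stride - pad + ki;
          size_t orow = (size_t)oh * oW;
          if (ih < 0 || ih >= H) {
            std::fill(cc + orow, cc + orow + oW, 0.f);
            continue;
          }
          const float* xr = xc + (size_t)ih * W;
          for (int ow = 0; ow < oW; ow++) {
            int iw = ow * stride - pad + kj;
            cc[orow + ow] = (iw < 0 || iw >= W) ? 0.f : xr[iw];
          }
        }
      }
  }
}

static void col2im_add(const fmat& dcol, int C, int H, int W, int k,
                       int stride, int pad, int oH, int oW, fmat& dX) {
  for (int c = 0; c < C; c++) {
    float* xc = dX.colptr(c);
    for (int ki = 0; ki < k; ki++)
      for (int kj = 0; kj < k; kj++) {
        const float* cc = dcol.colptr((size_t)c * k * k + (size_t)ki * k + kj);
        for (int oh = 0; oh < oH; oh++) {
          int ih = oh * stride - pad + ki;
          if (ih < 0 || ih >= H) continue;
          float* xr = xc + (size_t)ih * W;
          for (int ow = 0; ow < oW; ow++) {
            int iw = ow * stride - pad + kj;
            if (iw < 0 || iw >= W) continue;
            xr[iw] += cc[(size_t)oh * oW + ow];
          }
        }
      }
  }
}

// ---------------------------------------------------------------------------
struct Conv {
  int inC = 0, outC = 0, k = 1, stride = 1, pad = 0;
  bool bias = false;
  fmat W;            // (inC*k*k) x outC
  frowvec b;
  fmat gW, vW;
  frowvec gb, vb;
  void init(int inC_, int outC_, int k_, int s, int p, bool bias_,
            std::mt19937& rng) {
    inC = inC_; outC = outC_; k = k_; stride = s; pad = p; bias = bias_;
    float sd = std::sqrt(2.f / ((float)inC * k * k));
    std::normal_distribution<float> nd(0.f, sd);
    W.set_size((arma::uword)inC * k * k, outC);
    for (arma::uword i = 0; i < W.n_elem; i++) W(i) = nd(rng);
    vW.zeros(W.n_rows, W.n_cols);
    if (bias) { b.zeros(outC); vb.zeros(outC); }
  }
  int oDim(int H) const { return (H + 2 * pad - k) / stride + 1; }
  void forward(const Ten& x, Ten& y) {
    int oh = oDim(x.H), ow = oDim(x.W);
    y.init(x.B, outC, oh, ow, false);
    fmat col;
    for (int bb = 0; bb < x.B; bb++) {
      im2col(x.d.slice(bb), inC, x.H, x.W, k, stride, pad, oh, ow, col);
      y.d.slice(bb) = col * W;
      if (bias) y.d.slice(bb).each_row() += b;
    }
  }
  void backward(const Ten& x, const Ten& dy, Ten& dx, bool need_dx) {
    int oh = dy.H, ow = dy.W;
    gW.zeros(W.n_rows, W.n_cols);
    if (bias) gb.zeros(outC);
    if (need_dx) dx.init(x.B, inC, x.H, x.W, true);
    fmat col, dcol;
    for (int bb = 0; bb < x.B; bb++) {
      im2col(x.d.slice(bb), inC, x.H, x.W, k, stride, pad, oh, ow, col);
      const fmat& dys = dy.d.slice(bb);
      gW += col.t() * dys;
      if (bias) gb += arma::sum(dys, 0);
      if (need_dx) {
        dcol = dys * W.t();
        col2im_add(dcol, inC, x.H, x.W, k, stride, pad, oh, ow, dx.d.slice(bb));
      }
    }
  }
  void sgd(float lr, float mu, float wd) {
    vW = mu * vW + gW + wd * W;
    W -= lr * vW;
    if (bias) { vb = mu * vb + gb; b -= lr * vb; }
  }
  size_t nparam() const { return W.n_elem + (bias ? (size_t)outC : 0); }
};

// ---------------------------------------------------------------------------
// batch normalization, optionally fused with ReLU
struct BNAct {
  int C = 0;
  bool relu = true;
  fvec g, bta, rm, rv, gg, gb, vg, vb, mean_, invstd_;
  float eps = 1e-5f, mom = 0.1f;
  void init(int C_, bool relu_) {
    C = C_; relu = relu_;
    g.ones(C); bta.zeros(C); rm.zeros(C); rv.ones(C);
    vg.zeros(C); vb.zeros(C);
  }
  void forward(const Ten& x, Ten& y, bool train) {
    y.init(x.B, C, x.H, x.W, false);
    size_t HW = x.HW();
    double N = (double)x.B * HW;
    mean_.set_size(C); invstd_.set_size(C);
    if (train) {
      for (int c = 0; c < C; c++) {
        double s = 0, s2 = 0;
        for (int bb = 0; bb < x.B; bb++) {
          const float* p = x.d.slice(bb).colptr(c);
          for (size_t i = 0; i < HW; i++) { s += p[i]; s2 += (double)p[i] * p[i]; }
        }
        double m = s / N, v = s2 / N - m * m;
        if (v < 0) v = 0;
        mean_(c) = (float)m;
        invstd_(c) = (float)(1.0 / std::sqrt(v + eps));
        rm(c) = (1.f - mom) * rm(c) + mom * (float)m;
        rv(c) = (1.f - mom) * rv(c) + mom * (float)v;
      }
    } else {
      for (int c = 0; c < C; c++) {
        mean_(c) = rm(c);
        invstd_(c) = 1.f / std::sqrt(rv(c) + eps);
      }
    }
    for (int bb = 0; bb < x.B; bb++) {
      const fmat& S = x.d.slice(bb);
      fmat& O = y.d.slice(bb);
      for (int c = 0; c < C; c++) {
        const float* p = S.colptr(c);
        float* q = O.colptr(c);
        float m = mean_(c), is = invstd_(c), gc = g(c), bc = bta(c);
        if (relu)
          for (size_t i = 0; i < HW; i++) {
            float t = (p[i] - m) * is * gc + bc;
            q[i] = t > 0.f ? t : 0.f;
          }
        else
          for (size_t i = 0; i < HW; i++) q[i] = (p[i] - m) * is * gc + bc;
      }
    }
  }
  // x: input, y: output of forward (for the ReLU mask)
  void backward(const Ten& x, const Ten& y, const Ten& dy, Ten& dx) {
    size_t HW = x.HW();
    double N = (double)x.B * HW;
    dx.init(x.B, C, x.H, x.W, false);
    gg.zeros(C); gb.zeros(C);
    for (int c = 0; c < C; c++) {
      float m = mean_(c), is = invstd_(c);
      double sdy = 0, sdyx = 0;
      for (int bb = 0; bb < x.B; bb++) {
        const float* p = x.d.slice(bb).colptr(c);
        const float* yy = y.d.slice(bb).colptr(c);
        const float* dd = dy.d.slice(bb).colptr(c);
        for (size_t i = 0; i < HW; i++) {
          float dv = (!relu || yy[i] > 0.f) ? dd[i] : 0.f;
          sdy += dv;
          sdyx += (double)dv * (p[i] - m) * is;
        }
      }
      gg(c) = (float)sdyx;
      gb(c) = (float)sdy;
      float k1 = g(c) * is;
      float c1 = (float)(sdy / N), c2 = (float)(sdyx / N);
      for (int bb = 0; bb < x.B; bb++) {
        const float* p = x.d.slice(bb).colptr(c);
        const float* yy = y.d.slice(bb).colptr(c);
        const float* dd = dy.d.slice(bb).colptr(c);
        float* q = dx.d.slice(bb).colptr(c);
        for (size_t i = 0; i < HW; i++) {
          float dv = (!relu || yy[i] > 0.f) ? dd[i] : 0.f;
          float xh = (p[i] - m) * is;
          q[i] = k1 * (dv - c1 - xh * c2);
        }
      }
    }
  }
  void sgd(float lr, float mu) {
    vg = mu * vg + gg; g -= lr * vg;
    vb = mu * vb + gb; bta -= lr * vb;
  }
  size_t nparam() const { return 2 * (size_t)C; }
};

// ---------------------------------------------------------------------------
struct MaxPool {
  int k = 3, stride = 2, pad = 1;
  arma::Cube<arma::uword> arg;
  void forward(const Ten& x, Ten& y) {
    int oh = (x.H + 2 * pad - k) / stride + 1;
    int ow = (x.W + 2 * pad - k) / stride + 1;
    y.init(x.B, x.C, oh, ow, false);
    arg.set_size((arma::uword)oh * ow, x.C, x.B);
    for (int bb = 0; bb < x.B; bb++) {
      const fmat& S = x.d.slice(bb);
      fmat& O = y.d.slice(bb);
      for (int c = 0; c < x.C; c++) {
        const float* p = S.colptr(c);
        float* q = O.colptr(c);
        arma::uword* am = arg.slice(bb).colptr(c);
        for (int u = 0; u < oh; u++)
          for (int v = 0; v < ow; v++) {
            float best = -std::numeric_limits<float>::infinity();
            size_t bidx = 0;
            for (int ki = 0; ki < k; ki++) {
              int ih = u * stride - pad + ki;
              if (ih < 0 || ih >= x.H) continue;
              for (int kj = 0; kj < k; kj++) {
                int iw = v * stride - pad + kj;
                if (iw < 0 || iw >= x.W) continue;
                float val = p[(size_t)ih * x.W + iw];
                if (val > best) { best = val; bidx = (size_t)ih * x.W + iw; }
              }
            }
            q[(size_t)u * ow + v] = best;
            am[(size_t)u * ow + v] = bidx;
          }
      }
    }
  }
  void backward(const Ten& x, const Ten& dy, Ten& dx) {
    dx.init(x.B, x.C, x.H, x.W, true);
    size_t oHW = dy.HW();
    for (int bb = 0; bb < x.B; bb++)
      for (int c = 0; c < x.C; c++) {
        const float* dd = dy.d.slice(bb).colptr(c);
        const arma::uword* am = arg.slice(bb).colptr(c);
        float* q = dx.d.slice(bb).colptr(c);
        for (size_t i = 0; i < oHW; i++) q[am[i]] += dd[i];
      }
  }
};

// ---------------------------------------------------------------------------
static inline float sigm(float v) { return 1.f / (1.f + std::exp(-v)); }

// CBAM: channel attention (shared bias-free 2-layer MLP over per-channel
// average- and max-pooled descriptors, summed, sigmoid), then spatial
// attention (k x k conv over channel-mean/max maps, sigmoid).
struct CBAM {
  int C = 0, r = 16, sk = 7;
  fmat W1, W2;     // W1: (C/r x C), W2: (C x C/r)
  fmat gW1, gW2, vW1, vW2;
  Conv sconv;      // 2 -> 1 channels
  // caches
  fmat savg, smax, h1a, h1m, att;  // (C|Cr) x B
  arma::umat amax;                 // C x B, input pixel index of channel max
  Ten y1, mten, zten;
  fmat sg;                         // HW x B spatial gate
  arma::umat cmax;                 // HW x B channel index of spatial max
  void init(int C_, int r_, int sk_, std::mt19937& rng) {
    C = C_; r = r_; sk = sk_;
    int Cr = C / r;
    float sd1 = std::sqrt(2.f / C), sd2 = std::sqrt(2.f / Cr);
    std::normal_distribution<float> n1(0.f, sd1), n2(0.f, sd2);
    W1.set_size(Cr, C);
    for (arma::uword i = 0; i < W1.n_elem; i++) W1(i) = n1(rng);
    W2.set_size(C, Cr);
    for (arma::uword i = 0; i < W2.n_elem; i++) W2(i) = n2(rng);
    vW1.zeros(W1.n_rows, W1.n_cols);
    vW2.zeros(W2.n_rows, W2.n_cols);
    sconv.init(2, 1, sk, 1, (sk - 1) / 2, true, rng);
  }
  void forward(const Ten& x, Ten& y) {
    size_t HW = x.HW();
    int B = x.B;
    savg.set_size(C, B); smax.set_size(C, B); amax.set_size(C, B);
    for (int bb = 0; bb < B; bb++) {
      const fmat& S = x.d.slice(bb);
      for (int c = 0; c < C; c++) {
        const float* p = S.colptr(c);
        double s = 0; float mx = p[0]; size_t ai = 0;
        for (size_t i = 0; i < HW; i++) {
          s += p[i];
          if (p[i] > mx) { mx = p[i]; ai = i; }
        }
        savg(c, bb) = (float)(s / HW); smax(c, bb) = mx; amax(c, bb) = ai;
      }
    }
    h1a = W1 * savg; h1a.transform([](float v) { return v > 0.f ? v : 0.f; });
    h1m = W1 * smax; h1m.transform([](float v) { return v > 0.f ? v : 0.f; });
    fmat pre = W2 * h1a + W2 * h1m;
    att = pre;
    att.transform([](float v) { return sigm(v); });
    y1.init(B, C, x.H, x.W, false);
    for (int bb = 0; bb < B; bb++)
      y1.d.slice(bb) = x.d.slice(bb) % arma::repmat(att.col(bb).t(), HW, 1);
    // spatial descriptors from the channel-gated map
    mten.init(B, 2, x.H, x.W, false);
    cmax.set_size(HW, B);
    for (int bb = 0; bb < B; bb++) {
      const fmat& S = y1.d.slice(bb);
      fmat& M = mten.d.slice(bb);
      for (size_t i = 0; i < HW; i++) {
        double s = 0; float mx = S(i, 0); arma::uword ci = 0;
        for (int c = 0; c < C; c++) {
          float v = S(i, c);
          s += v;
          if (v > mx) { mx = v; ci = c; }
        }
        M(i, 0) = (float)(s / C); M(i, 1) = mx; cmax(i, bb) = ci;
      }
    }
    sconv.forward(mten, zten);
    sg.set_size(HW, B);
    for (int bb = 0; bb < B; bb++)
      for (size_t i = 0; i < HW; i++) sg(i, bb) = sigm(zten.d.slice(bb)(i, 0));
    y.init(B, C, x.H, x.W, false);
    for (int bb = 0; bb < B; bb++)
      y.d.slice(bb) = y1.d.slice(bb).each_col() % sg.col(bb);
  }
  void backward(const Ten& x, const Ten& dy, Ten& dx) {
    size_t HW = x.HW();
    int B = x.B, Cr = C / r;
    gW1.zeros(W1.n_rows, W1.n_cols); gW2.zeros(W2.n_rows, W2.n_cols);
    dx.init(B, C, x.H, x.W, false);
    Ten dz; dz.init(B, 1, x.H, x.W, false);
    fmat dY1all((arma::uword)HW, C);
    std::vector<fmat> dY1store(B);
    for (int bb = 0; bb < B; bb++) {
      const fmat& DY = dy.d.slice(bb);
      const fmat& Y1 = y1.d.slice(bb);
      fvec ds = arma::sum(DY % Y1, 1);
      dY1store[bb] = DY.each_col() % sg.col(bb);
      for (size_t i = 0; i < HW; i++) {
        float s = sg(i, bb);
        dz.d.slice(bb)(i, 0) = ds(i) * s * (1.f - s);
      }
    }
    Ten dm;
    sconv.backward(mten, dz, dm, true);
    for (int bb = 0; bb < B; bb++) {
      fmat& dY1 = dY1store[bb];
      const fmat& DM = dm.d.slice(bb);
      fvec dmavg = DM.col(0) / (float)C;
      dY1.each_col() += dmavg;
      for (size_t i = 0; i < HW; i++) dY1(i, cmax(i, bb)) += DM(i, 1);
      const fmat& X = x.d.slice(bb);
      frowvec da = arma::sum(dY1 % X, 0);
      dx.d.slice(bb) = dY1.each_row() % att.col(bb).t();
      fvec dpre(C);
      for (int c = 0; c < C; c++) {
        float a = att(c, bb);
        dpre(c) = da(c) * a * (1.f - a);
      }
      fvec dh1a = W2.t() * dpre;
      fvec dh1m = dh1a;  // shared W2
      for (int j = 0; j < Cr; j++) {
        if (h1a(j, bb) <= 0.f) dh1a(j) = 0.f;
        if (h1m(j, bb) <= 0.f) dh1m(j) = 0.f;
      }
      gW2 += dpre * (h1a.col(bb) + h1m.col(bb)).t();
      gW1 += dh1a * savg.col(bb).t() + dh1m * smax.col(bb).t();
      fvec dsavg = W1.t() * dh1a;
      fvec dsmax = W1.t() * dh1m;
      dx.d.slice(bb).each_row() += (dsavg / (float)HW).t();
      for (int c = 0; c < C; c++) dx.d.slice(bb)(amax(c, bb), c) += dsmax(c);
    }
  }
  void sgd(float lr, float mu, float wd) {
    vW1 = mu * vW1 + gW1 + wd * W1; W1 -= lr * vW1;
    vW2 = mu * vW2 + gW2 + wd * W2; W2 -= lr * vW2;
    sconv.sgd(lr, mu, wd);
  }
  size_t nparam() const { return W1.n_elem + W2.n_elem + sconv.nparam(); }
};

// ---------------------------------------------------------------------------
// "Stationary" residual block (pre-activation bottleneck): norm/ReLU moved
// before the first 1x1 conv; no normalization after the last 1x1 conv
// (which therefore carries a bias). Projection shortcut keeps its norm.
struct SRB {
  int inC = 0, midC = 0, outC = 0, stride = 1;
  bool proj = false;
  BNAct bn1, bn2, bn3, bns;
  Conv c1, c2, c3, cs;
  Ten a1, z1, a2, z2, a3, scv, sco;
  void init(int inC_, int midC_, int outC_, int stride_, std::mt19937& rng) {
    inC = inC_; midC = midC_; outC = outC_; stride = stride_;
    proj = (inC != outC) || (stride != 1);
    bn1.init(inC, true);
    c1.init(inC, midC, 1, 1, 0, false, rng);
    bn2.init(midC, true);
    c2.init(midC, midC, 3, stride, 1, false, rng);
    bn3.init(midC, true);
    c3.init(midC, outC, 1, 1, 0, true, rng);
    if (proj) {
      cs.init(inC, outC, 1, stride, 0, false, rng);
      bns.init(outC, false);
    }
  }
  void forward(const Ten& x, Ten& y, bool train) {
    bn1.forward(x, a1, train);
    c1.forward(a1, z1);
    bn2.forward(z1, a2, train);
    c2.forward(a2, z2);
    bn3.forward(z2, a3, train);
    c3.forward(a3, y);
    if (proj) {
      cs.forward(x, scv);
      bns.forward(scv, sco, train);
      y.d += sco.d;
    } else {
      y.d += x.d;
    }
  }
  void backward(const Ten& x, const Ten& dy, Ten& dx) {
    Ten da3, dz2, da2, dz1, da1;
    c3.backward(a3, dy, da3, true);
    bn3.backward(z2, a3, da3, dz2);
    c2.backward(a2, dz2, da2, true);
    bn2.backward(z1, a2, da2, dz1);
    c1.backward(a1, dz1, da1, true);
    bn1.backward(x, a1, da1, dx);
    if (proj) {
      Ten dscv, dxs;
      bns.backward(scv, sco, dy, dscv);
      cs.backward(x, dscv, dxs, true);
      dx.d += dxs.d;
    } else {
      dx.d += dy.d;
    }
  }
  void sgd(float lr, float mu, float wd) {
    bn1.sgd(lr, mu); c1.sgd(lr, mu, wd);
    bn2.sgd(lr, mu); c2.sgd(lr, mu, wd);
    bn3.sgd(lr, mu); c3.sgd(lr, mu, wd);
    if (proj) { cs.sgd(lr, mu, wd); bns.sgd(lr, mu); }
  }
  size_t nparam() const {
    size_t n = bn1.nparam() + bn2.nparam() + bn3.nparam() +
               c1.nparam() + c2.nparam() + c3.nparam();
    if (proj) n += cs.nparam() + bns.nparam();
    return n;
  }
};

// ---------------------------------------------------------------------------
// bilinear interpolation weights of one axis (half-pixel centers, edge clamp)
static void axis_weights(int inN, int outN, std::vector<int>& i0,
                         std::vector<int>& i1, std::vector<float>& w1) {
  i0.resize(outN); i1.resize(outN); w1.resize(outN);
  for (int u = 0; u < outN; u++) {
    double src = ((double)u + 0.5) * inN / outN - 0.5;
    if (src < 0) src = 0;
    if (src > inN - 1) src = inN - 1;
    int a = (int)std::floor(src);
    int b = std::min(a + 1, inN - 1);
    i0[u] = a; i1[u] = b; w1[u] = (float)(src - a);
  }
}

// per-input-pixel weight vector w with mean(upsample(X)) == dot(vec(X), w)
static fvec gap_weights(int inH, int inW, int outH, int outW) {
  std::vector<int> r0, r1, c0, c1;
  std::vector<float> rw, cw;
  axis_weights(inH, outH, r0, r1, rw);
  axis_weights(inW, outW, c0, c1, cw);
  fvec wr(inH, arma::fill::zeros), wc(inW, arma::fill::zeros);
  for (int u = 0; u < outH; u++) {
    wr(r0[u]) += (1.f - rw[u]) / outH;
    wr(r1[u]) += rw[u] / outH;
  }
  for (int v = 0; v < outW; v++) {
    wc(c0[v]) += (1.f - cw[v]) / outW;
    wc(c1[v]) += cw[v] / outW;
  }
  fvec w((arma::uword)inH * inW);
  for (int i = 0; i < inH; i++)
    for (int j = 0; j < inW; j++) w((size_t)i * inW + j) = wr(i) * wc(j);
  return w;
}

// ---------------------------------------------------------------------------
struct Net {
  int inC = 1, nclass = 2, cbam_r = 16, cbam_k = 7;
  std::vector<int> counts{1, 1, 1, 1};
  std::vector<int> midC{64, 128, 256, 512};
  std::vector<int> outCh{256, 512, 1024, 2048};
  int stemC = 64;
  Conv stemconv; BNAct stembn; CBAM cbam; MaxPool pool;
  std::vector<SRB> blocks;
  int x3_idx = 0, featdim = 0;
  fmat Wfc, gWfc, vWfc;
  frowvec bfc, gbfc, vbfc;
  // forward caches
  Ten x_in, t_sc, t_sa, X0, t_pool;
  std::vector<Ten> bo;
  fmat feats, logits;
  fvec wg3, wg6;

  void create(int inC_, std::vector<int> counts_, int cbam_r_, int cbam_k_,
              int nclass_, unsigned seed) {
    inC = inC_; counts = counts_; cbam_r = cbam_r_; cbam_k = cbam_k_;
    nclass = nclass_;
    std::mt19937 rng(seed);
    stemconv.init(inC, stemC, 7, 2, 3, false, rng);
    stembn.init(stemC, true);
    cbam.init(stemC, cbam_r, cbam_k, rng);
    blocks.clear();
    for (int s = 0; s < 4; s++)
      for (int i = 0; i < counts[s]; i++) {
        int in = (i == 0) ? (s == 0 ? stemC : outCh[s - 1]) : outCh[s];
        int st = (i == 0 && s > 0) ? 2 : 1;
        SRB blk;
        blk.init(in, midC[s], outCh[s], st, rng);
        blocks.push_back(std::move(blk));
      }
    x3_idx = counts[0] - 1;
    featdim = stemC + outCh[0] + outCh[3];
    std::normal_distribution<float> nd(0.f, 0.01f);
    Wfc.set_size(featdim, nclass);
    for (arma::uword i = 0; i < Wfc.n_elem; i++) Wfc(i) = nd(rng);
    bfc.zeros(nclass);
    vWfc.zeros(featdim, nclass); vbfc.zeros(nclass);
  }

  void forward(const Ten& x, bool train) {
    if (x.C != inC) stop("input has %d channels; model expects %d", x.C, inC);
    if (x.H != 224 || x.W != 224)
      stop("input spatial size is %dx%d; expected 224x224", x.H, x.W);
    x_in = x;
    stemconv.forward(x_in, t_sc);
    stembn.forward(t_sc, t_sa, train);
    cbam.forward(t_sa, X0);
    pool.forward(X0, t_pool);
    bo.resize(blocks.size());
    const Ten* cur = &t_pool;
    for (size_t i = 0; i < blocks.size(); i++) {
      blocks[i].forward(*cur, bo[i], train);
      cur = &bo[i];
    }
    const Ten& X3 = bo[x3_idx];
    const Ten& X6 = bo.back();
    wg3 = gap_weights(X3.H, X3.W, X0.H, X0.W);
    wg6 = gap_weights(X6.H, X6.W, X0.H, X0.W);
    int B = x.B;
    feats.set_size(B, featdim);
    for (int bb = 0; bb < B; bb++) {
      feats(bb, arma::span(0, stemC - 1)) = arma::mean(X0.d.slice(bb), 0);
      feats(bb, arma::span(stemC, stemC + outCh[0] - 1)) =
          wg3.t() * X3.d.slice(bb);
      feats(bb, arma::span(stemC + outCh[0], featdim - 1)) =
          wg6.t() * X6.d.slice(bb);
    }
    logits = feats * Wfc;
    logits.each_row() += bfc;
  }

  double train_batch(const Ten& x, const std::vector<int>& y, float lr,
                     float mu, float wd) {
    forward(x, true);
    int B = x.B;
    fmat dlogits(B, nclass);
    double loss = 0;
    for (int bb = 0; bb < B; bb++) {
      float m = logits.row(bb).max();
      double Z = 0;
      for (int k2 = 0; k2 < nclass; k2++) Z += std::exp((double)logits(bb, k2) - m);
      loss += -((double)logits(bb, y[bb]) - m - std::log(Z));
      for (int k2 = 0; k2 < nclass; k2++) {
        double p = std::exp((double)logits(bb, k2) - m) / Z;
        dlogits(bb, k2) = (float)((p - (k2 == y[bb] ? 1.0 : 0.0)) / B);
      }
    }
    loss /= B;
    // head backward
    gWfc = feats.t() * dlogits;
    gbfc = arma::sum(dlogits, 0);
    fmat dfeats = dlogits * Wfc.t();  // B x featdim
    const Ten& X3 = bo[x3_idx];
    const Ten& X6 = bo.back();
    Ten dX6; dX6.init(B, X6.C, X6.H, X6.W, false);
    Ten dX3h; dX3h.init(B, X3.C, X3.H, X3.W, false);
    Ten dX0h; dX0h.init(B, X0.C, X0.H, X0.W, false);
    float invHW0 = 1.f / (float)X0.HW();
    for (int bb = 0; bb < B; bb++) {
      for (int c = 0; c < X6.C; c++)
        dX6.d.slice(bb).col(c) = wg6 * dfeats(bb, stemC + outCh[0] + c);
      for (int c = 0; c < X3.C; c++)
        dX3h.d.slice(bb).col(c) = wg3 * dfeats(bb, stemC + c);
      for (int c = 0; c < X0.C; c++)
        dX0h.d.slice(bb).col(c).fill(dfeats(bb, c) * invHW0);
    }
    Ten dcur = std::move(dX6), dprev;
    for (int i = (int)blocks.size() - 1; i >= 0; i--) {
      if (i == x3_idx) dcur.d += dX3h.d;
      const Ten& xin = (i == 0) ? t_pool : bo[i - 1];
      blocks[i].backward(xin, dcur, dprev);
      dcur = std::move(dprev);
    }
    Ten dxp;
    pool.backward(X0, dcur, dxp);
    dxp.d += dX0h.d;
    Ten dsa, dsc, dumm;
    cbam.backward(t_sa, dxp, dsa);
    stembn.backward(t_sc, t_sa, dsa, dsc);
    stemconv.backward(x_in, dsc, dumm, false);
    // parameter update
    stemconv.sgd(lr, mu, wd);
    stembn.sgd(lr, mu);
    cbam.sgd(lr, mu, wd);
    for (auto& b : blocks) b.sgd(lr, mu, wd);
    vWfc = mu * vWfc + gWfc + wd * Wfc; Wfc -= lr * vWfc;
    vbfc = mu * vbfc + gbfc; bfc -= lr * vbfc;
    return loss;
  }

  size_t nparam() const {
    size_t n = stemconv.nparam() + stembn.nparam() + cbam.nparam() +
               Wfc.n_elem + bfc.n_elem;
    for (const auto& b : blocks) n += b.nparam();
    return n;
  }
};

// ---------------------------------------------------------------------------
// R interface helpers
static NumericMatrix fmat_to_r(const fmat& M) {
  NumericMatrix out(M.n_rows, M.n_cols);
  for (arma::uword j = 0; j < M.n_cols; j++)
    for (arma::uword i = 0; i < M.n_rows; i++) out(i, j) = M(i, j);
  return out;
}
static NumericVector fvec_to_r(const fvec& v) {
  NumericVector out(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; i++) out[i] = v(i);
  return out;
}
static NumericVector frow_to_r(const frowvec& v) {
  NumericVector out(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; i++) out[i] = v(i);
  return out;
}
static fmat r_to_fmat(SEXP s) {
  NumericMatrix M(s);
  fmat out(M.nrow(), M.ncol());
  for (int j = 0; j < M.ncol(); j++)
    for (int i = 0; i < M.nrow(); i++) out(i, j) = (float)M(i, j);
  return out;
}
static fvec r_to_fvec(SEXP s) {
  NumericVector v(s);
  fvec out(v.size());
  for (int i = 0; i < v.size(); i++) out(i) = (float)v[i];
  return out;
}
static frowvec r_to_frow(SEXP s) {
  NumericVector v(s);
  frowvec out(v.size());
  for (int i = 0; i < v.size(); i++) out(i) = (float)v[i];
  return out;
}

// [[Rcpp::export]]
SEXP sff_create(List config, int seed) {
  std::vector<int> counts = as<std::vector<int>>(config["stage_block_counts"]);
  int inC = as<int>(config["input_channels"]);
  int r = as<int>(config["cbam_reduction"]);
  int sk = as<int>(config["cbam_spatial_kernel"]);
  int nc = as<int>(config["num_classes"]);
  Net* net = new Net();
  net->create(inC, counts, r, sk, nc, (unsigned)seed);
  XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
List sff_forward(SEXP ptr_, NumericVector x, bool train = false,
                 bool want_features = false) {
  XPtr<Net> ptr(ptr_);
  Ten t = r_to_ten(x);
  ptr->forward(t, train);
  List out = List::create(_["logits"] = fmat_to_r(ptr->logits));
  if (want_features) {
    out["X0"] = ten_to_r(ptr->X0);
    out["X3"] = ten_to_r(ptr->bo[ptr->x3_idx]);
    out["X6"] = ten_to_r(ptr->bo.back());
  }
  return out;
}

// [[Rcpp::export]]
NumericVector sff_stem_forward(SEXP ptr_, NumericVector x) {
  XPtr<Net> ptr(ptr_);
  Ten t = r_to_ten(x);
  if (t.H != 224 || t.W != 224)
    stop("input spatial size is %dx%d; expected 224x224", t.H, t.W);
  Ten sc, sa, x0;
  ptr->stemconv.forward(t, sc);
  ptr->stembn.forward(sc, sa, false);
  ptr->cbam.forward(sa, x0);
  return ten_to_r(x0);
}

// [[Rcpp::export]]
double sff_train_batch(SEXP ptr_, NumericVector x, IntegerVector y,
                       double lr, double momentum, double weight_decay) {
  XPtr<Net> ptr(ptr_);
  Ten t = r_to_ten(x);
  std::vector<int> yy(y.begin(), y.end());
  return ptr->train_batch(t, yy, (float)lr, (float)momentum,
                          (float)weight_decay);
}

// [[Rcpp::export]]
double sff_param_count(SEXP ptr_) {
  XPtr<Net> ptr(ptr_);
  return (double)ptr->nparam();
}

// [[Rcpp::export]]
List sff_get_weights(SEXP ptr_) {
  XPtr<Net> ptr(ptr_);
  Net& n = *ptr;
  List w;
  w["stem.conv.W"] = fmat_to_r(n.stemconv.W);
  w["stem.bn.gamma"] = fvec_to_r(n.stembn.g);
  w["stem.bn.beta"] = fvec_to_r(n.stembn.bta);
  w["stem.bn.rm"] = fvec_to_r(n.stembn.rm);
  w["stem.bn.rv"] = fvec_to_r(n.stembn.rv);
  w["stem.cbam.W1"] = fmat_to_r(n.cbam.W1);
  w["stem.cbam.W2"] = fmat_to_r(n.cbam.W2);
  w["stem.cbam.sconv.W"] = fmat_to_r(n.cbam.sconv.W);
  w["stem.cbam.sconv.b"] = frow_to_r(n.cbam.sconv.b);
  for (size_t i = 0; i < n.blocks.size(); i++) {
    SRB& b = n.blocks[i];
    std::string p = "block" + std::to_string(i + 1) + ".";
    auto putbn = [&](const std::string& nm, BNAct& bn) {
      w[p + nm + ".gamma"] = fvec_to_r(bn.g);
      w[p + nm + ".beta"] = fvec_to_r(bn.bta);
      w[p + nm + ".rm"] = fvec_to_r(bn.rm);
      w[p + nm + ".rv"] = fvec_to_r(bn.rv);
    };
    putbn("bn1", b.bn1);
    w[p + "conv1.W"] = fmat_to_r(b.c1.W);
    putbn("bn2", b.bn2);
    w[p + "conv2.W"] = fmat_to_r(b.c2.W);
    putbn("bn3", b.bn3);
    w[p + "conv3.W"] = fmat_to_r(b.c3.W);
    w[p + "conv3.b"] = frow_to_r(b.c3.b);
    if (b.proj) {
      w[p + "shortcut.conv.W"] = fmat_to_r(b.cs.W);
      putbn("shortcut.bn", b.bns);
    }
  }
  w["fc.W"] = fmat_to_r(n.Wfc);
  w["fc.b"] = frow_to_r(n.bfc);
  return w;
}

// [[Rcpp::export]]
void sff_set_weights(SEXP ptr_, List w) {
  XPtr<Net> ptr(ptr_);
  Net& n = *ptr;
  auto getm = [&](const std::string& nm, fmat& dst) {
    if (!w.containsElementNamed(nm.c_str())) stop("missing weight '%s'", nm);
    fmat v = r_to_fmat(w[nm]);
    if (v.n_rows != dst.n_rows || v.n_cols != dst.n_cols)
      stop("shape mismatch for '%s'", nm);
    dst = v;
  };
  auto getv = [&](const std::string& nm, fvec& dst) {
    if (!w.containsElementNamed(nm.c_str())) stop("missing weight '%s'", nm);
    fvec v = r_to_fvec(w[nm]);
    if (v.n_elem != dst.n_elem) stop("shape mismatch for '%s'", nm);
    dst = v;
  };
  auto getr = [&](const std::string& nm, frowvec& dst) {
    if (!w.containsElementNamed(nm.c_str())) stop("missing weight '%s'", nm);
    frowvec v = r_to_frow(w[nm]);
    if (v.n_elem != dst.n_elem) stop("shape mismatch for '%s'", nm);
    dst = v;
  };
  getm("stem.conv.W", n.stemconv.W);
  getv("stem.bn.gamma", n.stembn.g);
  getv("stem.bn.beta", n.stembn.bta);
  getv("stem.bn.rm", n.stembn.rm);
  getv("stem.bn.rv", n.stembn.rv);
  getm("stem.cbam.W1", n.cbam.W1);
  getm("stem.cbam.W2", n.cbam.W2);
  getm("stem.cbam.sconv.W", n.cbam.sconv.W);
  getr("stem.cbam.sconv.b", n.cbam.sconv.b);
  for (size_t i = 0; i < n.blocks.size(); i++) {
    SRB& b = n.blocks[i];
    std::string p = "block" + std::to_string(i + 1) + ".";
    auto getbn = [&](const std::string& nm, BNAct& bn) {
      getv(p + nm + ".gamma", bn.g);
      getv(p + nm + ".beta", bn.bta);
      getv(p + nm + ".rm", bn.rm);
      getv(p + nm + ".rv", bn.rv);
    };
    getbn("bn1", b.bn1);
    getm(p + "conv1.W", b.c1.W);
    getbn("bn2", b.bn2);
    getm(p + "conv2.W", b.c2.W);
    getbn("bn3", b.bn3);
    getm(p + "conv3.W", b.c3.W);
    getr(p + "conv3.b", b.c3.b);
    if (b.proj) {
      getm(p + "shortcut.conv.W", b.cs.W);
      getbn("shortcut.bn", b.bns);
    }
  }
  getm("fc.W", n.Wfc);
  getr("fc.b", n.bfc);
}

// ---------------------------------------------------------------------------
// standalone building blocks for inspection and testing

// [[Rcpp::export]]
NumericVector cpp_cbam_forward(NumericVector x, NumericMatrix W1,
                               NumericMatrix W2, NumericMatrix convW,
                               NumericVector convb, int spatial_kernel) {
  Ten t = r_to_ten(x);
  int C = t.C;
  int Cr = W1.nrow();
  if (C % Cr != 0 || W1.ncol() != C)
    stop("channel MLP shape does not match %d channels", C);
  CBAM cb;
  std::mt19937 rng(0);
  cb.init(C, C / Cr, spatial_kernel, rng);
  cb.W1 = r_to_fmat(W1);
  cb.W2 = r_to_fmat(W2);
  cb.sconv.W = r_to_fmat(convW);
  cb.sconv.b = r_to_frow(convb);
  Ten y;
  cb.forward(t, y);
  return ten_to_r(y);
}

// [[Rcpp::export]]
List cpp_cbam_attention(NumericVector x, NumericMatrix W1, NumericMatrix W2,
                        NumericMatrix convW, NumericVector convb,
                        int spatial_kernel) {
  Ten t = r_to_ten(x);
  int C = t.C, Cr = W1.nrow();
  CBAM cb;
  std::mt19937 rng(0);
  cb.init(C, C / Cr, spatial_kernel, rng);
  cb.W1 = r_to_fmat(W1);
  cb.W2 = r_to_fmat(W2);
  cb.sconv.W = r_to_fmat(convW);
  cb.sconv.b = r_to_frow(convb);
  Ten y;
  cb.forward(t, y);
  return List::create(_["channel"] = fmat_to_r(cb.att),
                      _["spatial"] = fmat_to_r(cb.sg));
}

// [[Rcpp::export]]
NumericVector cpp_srb_forward(NumericVector x, List w, int mid_ch, int out_ch,
                              int stride) {
  Ten t = r_to_ten(x);
  SRB b;
  std::mt19937 rng(0);
  b.init(t.C, mid_ch, out_ch, stride, rng);
  auto bn = [&](const std::string& nm, BNAct& dst) {
    List l = w[nm];
    dst.g = r_to_fvec(l["gamma"]); dst.bta = r_to_fvec(l["beta"]);
    dst.rm = r_to_fvec(l["rm"]); dst.rv = r_to_fvec(l["rv"]);
  };
  bn("bn1", b.bn1);
  b.c1.W = r_to_fmat(w["conv1.W"]);
  bn("bn2", b.bn2);
  b.c2.W = r_to_fmat(w["conv2.W"]);
  bn("bn3", b.bn3);
  b.c3.W = r_to_fmat(w["conv3.W"]);
  b.c3.b = r_to_frow(w["conv3.b"]);
  if (b.proj) {
    b.cs.W = r_to_fmat(w["shortcut.conv.W"]);
    bn("shortcut.bn", b.bns);
  }
  Ten y;
  b.forward(t, y, false);
  return ten_to_r(y);
}

// [[Rcpp::export]]
List cpp_srb_init(NumericVector dims, int mid_ch, int out_ch, int stride,
                  int seed) {
  // dims = c(in_ch); returns freshly initialized weights as a named list
  SRB b;
  std::mt19937 rng((unsigned)seed);
  b.init((int)dims[0], mid_ch, out_ch, stride, rng);
  auto bn = [&](BNAct& bnl) {
    return List::create(_["gamma"] = fvec_to_r(bnl.g),
                        _["beta"] = fvec_to_r(bnl.bta),
                        _["rm"] = fvec_to_r(bnl.rm),
                        _["rv"] = fvec_to_r(bnl.rv));
  };
  List w;
  w["bn1"] = bn(b.bn1);
  w["conv1.W"] = fmat_to_r(b.c1.W);
  w["bn2"] = bn(b.bn2);
  w["conv2.W"] = fmat_to_r(b.c2.W);
  w["bn3"] = bn(b.bn3);
  w["conv3.W"] = fmat_to_r(b.c3.W);
  w["conv3.b"] = frow_to_r(b.c3.b);
  if (b.proj) {
    w["shortcut.conv.W"] = fmat_to_r(b.cs.W);
    w["shortcut.bn"] = bn(b.bns);
  }
  return w;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix img, int out_h, int out_w) {
  int H = img.nrow(), W = img.ncol();
  std::vector<int> r0, r1, c0, c1;
  std::vector<float> rw, cw;
  axis_weights(H, out_h, r0, r1, rw);
  axis_weights(W, out_w, c0, c1, cw);
  NumericMatrix out(out_h, out_w);
  for (int u = 0; u < out_h; u++)
    for (int v = 0; v < out_w; v++) {
      double a = img(r0[u], c0[v]) * (1.0 - rw[u]) * (1.0 - cw[v]) +
                 img(r1[u], c0[v]) * rw[u] * (1.0 - cw[v]) +
                 img(r0[u], c1[v]) * (1.0 - rw[u]) * cw[v] +
                 img(r1[u], c1[v]) * rw[u] * cw[v];
      out(u, v) = a;
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample4d(NumericVector x, int out_h, int out_w) {
  Ten t = r_to_ten(x);
  std::vector<int> r0, r1, c0, c1;
  std::vector<float> rw, cw;
  axis_weights(t.H, out_h, r0, r1, rw);
  axis_weights(t.W, out_w, c0, c1, cw);
  Ten y; y.init(t.B, t.C, out_h, out_w, false);
  for (int bb = 0; bb < t.B; bb++)
    for (int c = 0; c < t.C; c++) {
      const float* p = t.d.slice(bb).colptr(c);
      float* q = y.d.slice(bb).colptr(c);
      for (int u = 0; u < out_h; u++)
        for (int v = 0; v < out_w; v++) {
          float a = p[(size_t)r0[u] * t.W + c0[v]] * (1.f - rw[u]) * (1.f - cw[v]) +
                    p[(size_t)r1[u] * t.W + c0[v]] * rw[u] * (1.f - cw[v]) +
                    p[(size_t)r0[u] * t.W + c1[v]] * (1.f - rw[u]) * cw[v] +
                    p[(size_t)r1[u] * t.W + c1[v]] * rw[u] * cw[v];
          q[(size_t)u * out_w + v] = a;
        }
    }
  return ten_to_r(y);
}

// inverse-map affine warp: src = M %*% c(r, c, 1); bilinear, zero fill
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(NumericMatrix img, NumericVector M,
                              int out_h, int out_w) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  double m0 = M[0], m1 = M[1], m2 = M[2], m3 = M[3], m4 = M[4], m5 = M[5];
  for (int r = 0; r < out_h; r++)
    for (int c = 0; c < out_w; c++) {
      double sr = m0 * r + m1 * c + m2;
      double sc = m3 * r + m4 * c + m5;
      if (sr < -1 || sr > H || sc < -1 || sc > W) { out(r, c) = 0; continue; }
      int i0 = (int)std::floor(sr), j0 = (int)std::floor(sc);
      double fr = sr - i0, fc2 = sc - j0;
      auto px = [&](int i, int j) -> double {
        if (i < 0 || i >= H || j < 0 || j >= W) return 0.0;
        return img(i, j);
      };
      out(r, c) = px(i0, j0) * (1 - fr) * (1 - fc2) +
                  px(i0 + 1, j0) * fr * (1 - fc2) +
                  px(i0, j0 + 1) * (1 - fr) * fc2 +
                  px(i0 + 1, j0 + 1) * fr * fc2;
    }
  return out;
}
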