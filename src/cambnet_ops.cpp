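// Low-level numeric kernels for the CAMBNET engine.
//
// Array layout convention (matching R column-major arrays):
//   feature maps  x : dim (H, W, C, N), h fastest
//   conv weights  w : dim (kh, kw, cg, Cout) with cg = Cin / groups
// Flattened kernel index for output channel oc:
//   ki + kh*(kj + kw*(c + cg*oc))  ==  kpart + K*oc,  K = kh*kw*cg

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
using namespace Rcpp;


static inline void set_dim4(NumericVector& v, int a, int b, int c, int d) {
  v.attr("dim") = IntegerVector::create(a, b, c, d);
}
static inline int out_size(int in, int k, int pad, int stride) {
  return (in + 2 * pad - k) / stride + 1;
}

// Build the im2col matrix (K x P) for one sample / one channel group.
// xg points at the first element (h=0,w=0) of the group's first channel;
// channels are contiguous with stride H*W.
static void im2col(const double* xg, int H, int W, int cg,
                   int kh, int kw, int ph, int pw, int stride,
                   int Ho, int Wo, arma::mat& col) {
  const int HW = H * W;
  for (int c = 0; c < cg; ++c) {
    const double* xc = xg + (size_t)c * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int jo = 0; jo < Wo; ++jo) {
          const int wi = jo * stride - pw + kj;
          double* cp = col.colptr(jo * Ho) + row; // advance by K per column
          if (wi < 0 || wi >= W) {
            for (int io = 0; io < Ho; ++io, cp += col.n_rows) *cp = 0.0;
          } else {
            const double* xcol = xc + (size_t)wi * H;
            for (int io = 0; io < Ho; ++io, cp += col.n_rows) {
              const int hi = io * stride - ph + ki;
              *cp = (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
            }
          }
        }
      }
    }
  }
}

// Scatter-add a gradient im2col matrix back into the input gradient.
static void col2im(const arma::mat& col, double* gxg, int H, int W, int cg,
                   int kh, int kw, int ph, int pw, int stride,
                   int Ho, int Wo) {
  const int HW = H * W;
  for (int c = 0; c < cg; ++c) {
    double* gxc = gxg + (size_t)c * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int jo = 0; jo < Wo; ++jo) {
          const int wi = jo * stride - pw + kj;
          if (wi < 0 || wi >= W) continue;
          const double* cp = col.colptr(jo * Ho) + row;
          double* gxcol = gxc + (size_t)wi * H;
          for (int io = 0; io < Ho; ++io, cp += col.n_rows) {
            const int hi = io * stride - ph + ki;
            if (hi >= 0 && hi < H) gxcol[hi] += *cp;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector bias,
                             int stride, int ph, int pw, int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], cg = wdim[2], Cout = wdim[3];
  if (cg * groups != C) stop("conv: channel/group mismatch");
  if (Cout % groups != 0) stop("conv: Cout not divisible by groups");
  const int cog = Cout / groups;
  const int Ho = out_size(H, kh, ph, stride);
  const int Wo = out_size(W, kw, pw, stride);
  const int P = Ho * Wo, K = kh * kw * cg, HW = H * W;
  NumericVector y((size_t)P * Cout * N);
  double* yp = y.begin();
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* bp = bias.begin();

  if (kh == 1 && kw == 1 && stride == 1 && groups == 1) {
    // pointwise conv: plain GEMM per sample
    arma::mat Wm(const_cast<double*>(wp), C, Cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat Xm(const_cast<double*>(xp) + (size_t)n * HW * C, HW, C, false, true);
      arma::mat Ym(yp + (size_t)n * P * Cout, P, Cout, false, true);
      Ym = Xm * Wm;
      Ym.each_row() += arma::rowvec(const_cast<double*>(bp), Cout, false, true);
    }
    set_dim4(y, Ho, Wo, Cout, N);
    return y;
  }

  if (groups == C && Cout == C && cg == 1 && stride == 1) {
    // depthwise, stride 1: shift-and-accumulate per channel
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < C; ++c) {
        arma::mat X(const_cast<double*>(xp) + ((size_t)n * C + c) * HW, H, W, false, true);
        arma::mat Y(yp + ((size_t)n * C + c) * (size_t)P, Ho, Wo, false, true);
        Y.fill(bp[c]);
        for (int kj = 0; kj < kw; ++kj) {
          for (int ki = 0; ki < kh; ++ki) {
            const double wv = wp[ki + kh * (kj + kw * c)];
            const int i0 = std::max(0, ph - ki), i1 = std::min(Ho - 1, H - 1 + ph - ki);
            const int j0 = std::max(0, pw - kj), j1 = std::min(Wo - 1, W - 1 + pw - kj);
            if (i0 > i1 || j0 > j1) continue;
            Y.submat(i0, j0, i1, j1) +=
              wv * X.submat(i0 - ph + ki, j0 - pw + kj, i1 - ph + ki, j1 - pw + kj);
          }
        }
      }
    }
    set_dim4(y, Ho, Wo, Cout, N);
    return y;
  }

  // generic grouped conv via im2col
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double* xg = xp + ((size_t)n * C + (size_t)g * cg) * HW;
      im2col(xg, H, W, cg, kh, kw, ph, pw, stride, Ho, Wo, col);
      arma::mat Wg(const_cast<double*>(wp) + (size_t)K * g * cog, K, cog, false, true);
      arma::mat Ym = col.t() * Wg; // P x cog
      for (int j = 0; j < cog; ++j) {
        const int oc = g * cog + j;
        double* yo = yp + ((size_t)n * Cout + oc) * (size_t)P;
        const double b = bp[oc];
        const double* src = Ym.colptr(j);
        for (int p = 0; p < P; ++p) yo[p] = src[p] + b;
      }
    }
  }
  set_dim4(y, Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector gy,
                    int stride, int ph, int pw, int groups) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], cg = wdim[2], Cout = wdim[3];
  const int cog = Cout / groups;
  const int Ho = out_size(H, kh, ph, stride);
  const int Wo = out_size(W, kw, pw, stride);
  const int P = Ho * Wo, K = kh * kw * cg, HW = H * W;
  NumericVector gx((size_t)HW * C * N);
  NumericVector gw(w.size());
  NumericVector gb(Cout);
  double* gxp = gx.begin();
  double* gwp = gw.begin();
  double* gbp = gb.begin();
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gyp = gy.begin();

  for (int oc = 0; oc < Cout; ++oc) {
    double s = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* go = gyp + ((size_t)n * Cout + oc) * (size_t)P;
      for (int p = 0; p < P; ++p) s += go[p];
    }
    gbp[oc] = s;
  }

  if (kh == 1 && kw == 1 && stride == 1 && groups == 1) {
    arma::mat Wm(const_cast<double*>(wp), C, Cout, false, true);
    arma::mat GW(gwp, C, Cout, false, true);
    for (int n = 0; n < N; ++n) {
      arma::mat Xm(const_cast<double*>(xp) + (size_t)n * HW * C, HW, C, false, true);
      arma::mat GY(const_cast<double*>(gyp) + (size_t)n * P * Cout, P, Cout, false, true);
      arma::mat GX(gxp + (size_t)n * HW * C, HW, C, false, true);
      GX = GY * Wm.t();
      GW += Xm.t() * GY;
    }
    gx.attr("dim") = xdim;
    gw.attr("dim") = wdim;
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }

  if (groups == C && Cout == C && cg == 1 && stride == 1) {
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < C; ++c) {
        arma::mat X(const_cast<double*>(xp) + ((size_t)n * C + c) * HW, H, W, false, true);
        arma::mat GY(const_cast<double*>(gyp) + ((size_t)n * C + c) * (size_t)P, Ho, Wo, false, true);
        arma::mat GX(gxp + ((size_t)n * C + c) * HW, H, W, false, true);
        for (int kj = 0; kj < kw; ++kj) {
          for (int ki = 0; ki < kh; ++ki) {
            const int i0 = std::max(0, ph - ki), i1 = std::min(Ho - 1, H - 1 + ph - ki);
            const int j0 = std::max(0, pw - kj), j1 = std::min(Wo - 1, W - 1 + pw - kj);
            if (i0 > i1 || j0 > j1) continue;
            const double wv = wp[ki + kh * (kj + kw * c)];
            GX.submat(i0 - ph + ki, j0 - pw + kj, i1 - ph + ki, j1 - pw + kj) +=
              wv * GY.submat(i0, j0, i1, j1);
            gwp[ki + kh * (kj + kw * c)] += arma::accu(
              X.submat(i0 - ph + ki, j0 - pw + kj, i1 - ph + ki, j1 - pw + kj) %
              GY.submat(i0, j0, i1, j1));
          }
        }
      }
    }
    gx.attr("dim") = xdim;
    gw.attr("dim") = wdim;
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }

  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const double* xg = xp + ((size_t)n * C + (size_t)g * cg) * HW;
      im2col(xg, H, W, cg, kh, kw, ph, pw, stride, Ho, Wo, col);
      arma::mat Wg(const_cast<double*>(wp) + (size_t)K * g * cog, K, cog, false, true);
      arma::mat GWg(gwp + (size_t)K * g * cog, K, cog, false, true);
      arma::mat GYg(const_cast<double*>(gyp) + ((size_t)n * Cout + (size_t)g * cog) * (size_t)P,
                    P, cog, false, true);
      GWg += col * GYg;
      arma::mat gcol = Wg * GYg.t(); // K x P
      double* gxg = gxp + ((size_t)n * C + (size_t)g * cg) * HW;
      col2im(gcol, gxg, H, W, cg, kh, kw, ph, pw, stride, Ho, Wo);
    }
  }
  gx.attr("dim") = xdim;
    gw.attr("dim") = wdim;
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled values and 0-based argmax
// indices into the flattened input (for the backward pass).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * (size_t)H * W;
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io, ++o) {
          const int h0 = 2 * io, w0 = 2 * jo;
          size_t best = base + (size_t)w0 * H + h0;
          double bv = xp[best];
          const size_t cand[3] = {base + (size_t)w0 * H + h0 + 1,
                                  base + (size_t)(w0 + 1) * H + h0,
                                  base + (size_t)(w0 + 1) * H + h0 + 1};
          for (int k = 0; k < 3; ++k) {
            if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
          }
          yp[o] = bv;
          ip[o] = (int)best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector gy, int xlen) {
  NumericVector gx(xlen);
  double* gxp = gx.begin();
  const double* gp = gy.begin();
  const int* ip = idx.begin();
  const R_xlen_t n = gy.size();
  for (R_xlen_t k = 0; k < n; ++k) gxp[ip[k]] += gp[k];
  return gx;
}

// Bilinear resize with half-pixel-center sampling (src = (dst+0.5)*scale-0.5,
// clamped to the frame). x: (H, W, C); output (outH, outW, C).
// [[Rcpp::export]]
NumericVector cpp_bilinear_resize(NumericVector x, IntegerVector xdim,
                                  int outH, int outW) {
  const int H = xdim[0], W = xdim[1], C = xdim[2];
  NumericVector y((size_t)outH * outW * C);
  const double sh = (double)H / outH, sw = (double)W / outW;
  std::vector<int> h0(outH), h1(outH); std::vector<double> fh(outH);
  std::vector<int> w0(outW), w1(outW); std::vector<double> fw(outW);
  for (int i = 0; i < outH; ++i) {
    double s = (i + 0.5) * sh - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    h0[i] = (int)std::floor(s); h1[i] = std::min(h0[i] + 1, H - 1); fh[i] = s - h0[i];
  }
  for (int j = 0; j < outW; ++j) {
    double s = (j + 0.5) * sw - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    w0[j] = (int)std::floor(s); w1[j] = std::min(w0[j] + 1, W - 1); fw[j] = s - w0[j];
  }
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * H * W;
    double* yc = yp + (size_t)c * outH * outW;
    for (int j = 0; j < outW; ++j) {
      const double* cl = xc + (size_t)w0[j] * H;
      const double* cr = xc + (size_t)w1[j] * H;
      for (int i = 0; i < outH; ++i) {
        const double top = cl[h0[i]] * (1 - fw[j]) + cr[h0[i]] * fw[j];
        const double bot = cl[h1[i]] * (1 - fw[j]) + cr[h1[i]] * fw[j];
        yc[(size_t)j * outH + i] = top * (1 - fh[i]) + bot * fh[i];
      }
    }
  }
  return y;
}

// 4-connected component of a binary mask containing (or nearest to) the seed.
// mask: integer matrix (0/1); seed given as 0-based (row, col).
// [[Rcpp::export]]
IntegerMatrix cpp_seed_component(IntegerMatrix mask, int seedRow, int seedCol) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix out(H, W);
  int sr = seedRow, sc = seedCol;
  if (sr < 0 || sr >= H || sc < 0 || sc >= W) stop("seed outside frame");
  if (mask(sr, sc) == 0) {
    // nearest positive pixel to the seed
    double best = 1e18; int br = -1, bc = -1;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        if (mask(i, j) != 0) {
          const double d = (double)(i - sr) * (i - sr) + (double)(j - sc) * (j - sc);
          if (d < best) { best = d; br = i; bc = j; }
        }
    if (br < 0) return out; // empty mask -> empty component
    sr = br; sc = bc;
  }
  std::queue<std::pair<int, int> > q;
  q.push(std::make_pair(sr, sc));
  out(sr, sc) = 1;
  const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int k = 0; k < 4; ++k) {
      const int r = p.first + dr[k], c = p.second + dc[k];
      if (r >= 0 && r < H && c >= 0 && c < W && mask(r, c) != 0 && out(r, c) == 0) {
        out(r, c) = 1;
        q.push(std::make_pair(r, c));
      }
    }
  }
  return out;
}

// ---- fused batch-norm (+ReLU) kernels -------------------------------------

// Forward. In training mode computes batch statistics over (H, W, N) per
// channel and returns updated running stats (with the unbiased-variance
// convention for the running value); in eval mode uses the running stats.
// [[Rcpp::export]]
List cpp_bn_relu_fwd(NumericVector x, IntegerVector xdim,
                     NumericVector gamma, NumericVector beta,
                     NumericVector rmean, NumericVector rvar,
                     double eps, double momentum, bool training, bool relu) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * N;
  NumericVector mean(C), var(C), invstd(C);
  NumericVector rmeanOut = clone(rmean), rvarOut = clone(rvar);
  const double* xp = x.begin();
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xc = xp + ((size_t)n * C + c) * HW;
        for (size_t i = 0; i < HW; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      }
      const double mu = s / m;
      double v = s2 / m - mu * mu;
      if (v < 0) v = 0;
      mean[c] = mu; var[c] = v;
      const double unbias = m > 1 ? m / (m - 1) : 1.0;
      rmeanOut[c] = (1 - momentum) * rmean[c] + momentum * mu;
      rvarOut[c] = (1 - momentum) * rvar[c] + momentum * v * unbias;
    }
  } else {
    for (int c = 0; c < C; ++c) { mean[c] = rmean[c]; var[c] = rvar[c]; }
  }
  NumericVector y(x.size()), xhat(x.size());
  double* yp = y.begin();
  double* hp = xhat.begin();
  for (int c = 0; c < C; ++c) {
    invstd[c] = 1.0 / std::sqrt(var[c] + eps);
    const double is = invstd[c], mu = mean[c], g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double* xc = xp + off;
      double* yc = yp + off;
      double* hc = hp + off;
      for (size_t i = 0; i < HW; ++i) {
        const double xh = (xc[i] - mu) * is;
        hc[i] = xh;
        double v = g * xh + b;
        if (relu && v < 0) v = 0;
        yc[i] = v;
      }
    }
  }
  y.attr("dim") = xdim;
  xhat.attr("dim") = xdim;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["rmean"] = rmeanOut, _["rvar"] = rvarOut);
}

// Backward through (ReLU o) BN. `y` is the forward output (for the ReLU
// mask); training selects batch-statistics backward vs eval (running
// stats treated as constants).
// [[Rcpp::export]]
List cpp_bn_relu_bwd(NumericVector gy, NumericVector y, NumericVector xhat,
                     IntegerVector xdim, NumericVector gamma,
                     NumericVector invstd, bool training, bool relu) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * N;
  NumericVector gx(gy.size()), ggamma(C), gbeta(C);
  const double* gp = gy.begin();
  const double* yp = y.begin();
  const double* hp = xhat.begin();
  double* op = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c];
    double sg = 0, sgx = 0; // sums of gxhat and gxhat*xhat
    double dgamma = 0, dbeta = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double* gc = gp + off;
      const double* yc = yp + off;
      const double* hc = hp + off;
      for (size_t i = 0; i < HW; ++i) {
        double g1 = gc[i];
        if (relu && yc[i] <= 0) g1 = 0;
        dgamma += g1 * hc[i];
        dbeta += g1;
        const double gxh = g1 * g;
        sg += gxh;
        sgx += gxh * hc[i];
      }
    }
    ggamma[c] = dgamma; gbeta[c] = dbeta;
    const double is = invstd[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double* gc = gp + off;
      const double* yc = yp + off;
      const double* hc = hp + off;
      double* oc = op + off;
      for (size_t i = 0; i < HW; ++i) {
        double g1 = gc[i];
        if (relu && yc[i] <= 0) g1 = 0;
        const double gxh = g1 * g;
        oc[i] = training ? (is / m) * (m * gxh - sg - hc[i] * sgx)
                         : gxh * is;
      }
    }
  }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// ---- broadcast / reduce helpers for the attention gates -------------------

// y = x * s[c, n] (scale every channel slice by a per-(channel, sample)
// scalar).
// [[Rcpp::export]]
NumericVector cpp_scale_cn(NumericVector x, IntegerVector xdim,
                           NumericMatrix s) {
  const int C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)xdim[0] * xdim[1];
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double v = s(c, n);
      const size_t off = ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) yp[off + i] = xp[off + i] * v;
    }
  y.attr("dim") = xdim;
  return y;
}

// out[c, n] = sum over space of a*b for that channel slice.
// [[Rcpp::export]]
NumericMatrix cpp_dot_cn(NumericVector a, NumericVector b,
                         IntegerVector xdim) {
  const int C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)xdim[0] * xdim[1];
  NumericMatrix out(C, N);
  const double* ap = a.begin();
  const double* bp = b.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      double s = 0;
      for (size_t i = 0; i < HW; ++i) s += ap[off + i] * bp[off + i];
      out(c, n) = s;
    }
  return out;
}

// out[c, n] = mean over space of x.
// [[Rcpp::export]]
NumericMatrix cpp_chan_mean_cn(NumericVector x, IntegerVector xdim) {
  const int C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)xdim[0] * xdim[1];
  NumericMatrix out(C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      double s = 0;
      for (size_t i = 0; i < HW; ++i) s += xp[off + i];
      out(c, n) = s / HW;
    }
  return out;
}

// broadcast v[c, n] / div over space.
// [[Rcpp::export]]
NumericVector cpp_bcast_cn(NumericMatrix v, IntegerVector xdim, double div) {
  const int C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)xdim[0] * xdim[1];
  NumericVector y((size_t)HW * C * N);
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double val = v(c, n) / div;
      const size_t off = ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) yp[off + i] = val;
    }
  y.attr("dim") = xdim;
  return y;
}

// y = x * s[hw, n] (scale every spatial position across channels).
// [[Rcpp::export]]
NumericVector cpp_scale_sp(NumericVector x, IntegerVector xdim,
                           NumericMatrix s) {
  const int C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)xdim[0] * xdim[1];
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    const double* sn = &s(0, n);
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) yp[off + i] = xp[off + i] * sn[i];
    }
  }
  y.attr("dim") = xdim;
  return y;
}

// out[hw, n] = sum over channels of a*b.
// [[Rcpp::export]]
NumericMatrix cpp_dot_sp(NumericVector a, NumericVector b,
                         IntegerVector xdim) {
  const int C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)xdim[0] * xdim[1];
  NumericMatrix out((int)HW, N);
  const double* ap = a.begin();
  const double* bp = b.begin();
  for (int n = 0; n < N; ++n) {
    double* on = &out(0, n);
    for (size_t i = 0; i < HW; ++i) on[i] = 0;
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) on[i] += ap[off + i] * bp[off + i];
    }
  }
  return out;
}

// out[hw, n] = mean over channels of x.
// [[Rcpp::export]]
NumericMatrix cpp_chan_collapse_mean(NumericVector x, IntegerVector xdim) {
  const int C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)xdim[0] * xdim[1];
  NumericMatrix out((int)HW, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    double* on = &out(0, n);
    for (size_t i = 0; i < HW; ++i) on[i] = 0;
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) on[i] += xp[off + i];
    }
    for (size_t i = 0; i < HW; ++i) on[i] /= C;
  }
  return out;
}

// broadcast s[hw, n] / div over channels.
// [[Rcpp::export]]
NumericVector cpp_bcast_sp(NumericMatrix s, IntegerVector xdim, double div) {
  const int C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)xdim[0] * xdim[1];
  NumericVector y((size_t)HW * C * N);
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    const double* sn = &s(0, n);
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) yp[off + i] = sn[i] / div;
    }
  }
  y.attr("dim") = xdim;
  return y;
}

// ---- dedicated depthwise convolution (any stride) -------------------------

// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector bias, int stride, int ph, int pw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1];
  const int Ho = out_size(H, kh, ph, stride), Wo = out_size(W, kw, pw, stride);
  const size_t HW = (size_t)H * W, P = (size_t)Ho * Wo;
  NumericVector y(P * C * N);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* X = xp + ((size_t)n * C + c) * HW;
      double* Y = yp + ((size_t)n * C + c) * P;
      const double b = bias[c];
      for (size_t i = 0; i < P; ++i) Y[i] = b;
      const double* wc = wp + (size_t)kh * kw * c;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const double wv = wc[ki + kh * kj];
          // output ranges with in-bounds input
          int jo0 = 0, jo1 = Wo - 1, io0 = 0, io1 = Ho - 1;
          while (jo0 <= jo1 && jo0 * stride - pw + kj < 0) ++jo0;
          while (jo1 >= jo0 && jo1 * stride - pw + kj >= W) --jo1;
          while (io0 <= io1 && io0 * stride - ph + ki < 0) ++io0;
          while (io1 >= io0 && io1 * stride - ph + ki >= H) --io1;
          for (int jo = jo0; jo <= jo1; ++jo) {
            const double* xcol = X + (size_t)(jo * stride - pw + kj) * H
                                   + (io0 * stride - ph + ki);
            double* ycol = Y + (size_t)jo * Ho + io0;
            const int len = io1 - io0 + 1;
            if (stride == 1) {
              for (int t = 0; t < len; ++t) ycol[t] += wv * xcol[t];
            } else {
              for (int t = 0; t < len; ++t) ycol[t] += wv * xcol[(size_t)t * stride];
            }
          }
        }
      }
    }
  }
  set_dim4(y, Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector gy, int stride, int ph, int pw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1];
  const int Ho = out_size(H, kh, ph, stride), Wo = out_size(W, kw, pw, stride);
  const size_t HW = (size_t)H * W, P = (size_t)Ho * Wo;
  NumericVector gx(x.size()), gw(w.size()), gb(C);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* X = xp + ((size_t)n * C + c) * HW;
      const double* GY = gp + ((size_t)n * C + c) * P;
      double* GX = gxp + ((size_t)n * C + c) * HW;
      double s = 0;
      for (size_t i = 0; i < P; ++i) s += GY[i];
      gb[c] += s;
      const double* wc = wp + (size_t)kh * kw * c;
      double* gwc = gwp + (size_t)kh * kw * c;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const double wv = wc[ki + kh * kj];
          double acc = 0;
          int jo0 = 0, jo1 = Wo - 1, io0 = 0, io1 = Ho - 1;
          while (jo0 <= jo1 && jo0 * stride - pw + kj < 0) ++jo0;
          while (jo1 >= jo0 && jo1 * stride - pw + kj >= W) --jo1;
          while (io0 <= io1 && io0 * stride - ph + ki < 0) ++io0;
          while (io1 >= io0 && io1 * stride - ph + ki >= H) --io1;
          for (int jo = jo0; jo <= jo1; ++jo) {
            const size_t xoff = (size_t)(jo * stride - pw + kj) * H
                                + (io0 * stride - ph + ki);
            const double* xcol = X + xoff;
            double* gxcol = GX + xoff;
            const double* gycol = GY + (size_t)jo * Ho + io0;
            const int len = io1 - io0 + 1;
            if (stride == 1) {
              for (int t = 0; t < len; ++t) {
                acc += xcol[t] * gycol[t];
                gxcol[t] += wv * gycol[t];
              }
            } else {
              for (int t = 0; t < len; ++t) {
                acc += xcol[(size_t)t * stride] * gycol[t];
                gxcol[(size_t)t * stride] += wv * gycol[t];
              }
            }
          }
          gwc[ki + kh * kj] += acc;
        }
      }
    }
  }
  gx.attr("dim") = xdim;
    gw.attr("dim") = wdim;
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
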