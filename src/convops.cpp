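// Low-level dense primitives for the residual-mesh encoder-decoder:
// stride-1 "same" convolution via im2col + BLAS GEMM, fused batch
// normalization + ReLU, 2x2/stride-2 max-pooling that records argmax
// indices, and the index-driven scatter/gather pair shared by
// max-unpooling and the pooling backward pass.
//
// Tensors are R arrays [H, W, C, N] (column-major). Weights are
// matrices Cout x (kh*kw*Cin) with column index q = ki + kh*(kj + kw*c).
// The im2col matrix is pixel-major (HW x kh*kw*Cin), so both the patch
// copies and the GEMM output land in contiguous memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector alloc4(int H, int W, int C, int N) {
  NumericVector y(R_xlen_t(H) * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

static IntegerVector alloc4i(int H, int W, int C, int N) {
  IntegerVector y(R_xlen_t(H) * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

static void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array [H, W, C, N]");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col for one sample. Out-of-image positions stay zero; the caller
// zero-fills `col` once and reuses it across samples (the zero pattern
// is identical for every sample).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int pad, arma::mat& col) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * c);
        double* cq = col.colptr(q);
        const int hlo = std::max(0, pad - ki);
        const int hhi = std::min(H, H + pad - ki);
        if (hhi <= hlo) continue;
        for (int w = 0; w < W; ++w) {
          const int ws = w - pad + kj;
          if (ws < 0 || ws >= W) continue;
          std::memcpy(cq + (size_t)w * H + hlo,
                      xc + (size_t)ws * H + hlo - pad + ki,
                      (size_t)(hhi - hlo) * sizeof(double));
        }
      }
    }
  }
}

// col2im: accumulate pixel-major column gradients back onto the grid.
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int pad, double* gx) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)c * HW;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * c);
        const double* cq = col.colptr(q);
        const int hlo = std::max(0, pad - ki);
        const int hhi = std::min(H, H + pad - ki);
        if (hhi <= hlo) continue;
        for (int w = 0; w < W; ++w) {
          const int ws = w - pad + kj;
          if (ws < 0 || ws >= W) continue;
          double* dst = gc + (size_t)ws * H + hlo - pad + ki;
          const double* src = cq + (size_t)w * H + hlo;
          for (int h = 0; h < hhi - hlo; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_forward(NumericVector x, NumericMatrix Wm,
                               NumericVector bias, int kh, int kw, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Cout = Wm.nrow();
  if (Wm.ncol() != kh * kw * C) stop("weight/input channel mismatch");
  const int HW = H * W;
  NumericVector y = alloc4(H, W, Cout, N);
  arma::mat Wa(Wm.begin(), Cout, Wm.ncol(), false, true);
  arma::rowvec b(bias.begin(), Cout);
  arma::mat col(HW, kh * kw * C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, pad, col);
    arma::mat out(y.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    out = col * Wa.t();                  // HW x Cout = sample plane block
    out.each_row() += b;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_backward(NumericVector x, NumericMatrix Wm, NumericVector gy,
                       int kh, int kw, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Cout = Wm.nrow();
  const int HW = H * W;
  arma::mat Wa(Wm.begin(), Cout, Wm.ncol(), false, true);
  NumericVector gx = alloc4(H, W, C, N);
  arma::mat gW(Cout, kh * kw * C, arma::fill::zeros);
  arma::rowvec gb(Cout, arma::fill::zeros);
  arma::mat col(HW, kh * kw * C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, pad, col);
    arma::mat gym(gy.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    gW += gym.t() * col;
    gb += arma::sum(gym, 0);
    arma::mat gcol = gym * Wa;           // HW x (kh*kw*C)
    col2im(gcol, H, W, C, kh, kw, pad, gx.begin() + (size_t)n * HW * C);
  }
  NumericVector gbv(gb.begin(), gb.end());
  return List::create(_["gx"] = gx,
                      _["gW"] = NumericMatrix(Cout, kh * kw * C, gW.begin()),
                      _["gb"] = gbv);
}

// Per-channel sums and sums of squares over (H, W, N).
// [[Rcpp::export]]
List cpp_channel_stats(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector s(C), s2(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * HW;
      double a = 0, b = 0;
      for (size_t p = 0; p < HW; ++p) { a += xs[p]; b += xs[p] * xs[p]; }
      s[c] += a; s2[c] += b;
    }
  }
  return List::create(_["sum"] = s, _["sumsq"] = s2);
}

// Fused batch-norm + ReLU forward given per-channel statistics:
// xhat = (x - mu) * invstd, y = max(gamma * xhat + beta, 0).
// [[Rcpp::export]]
List cpp_bnrelu_forward(NumericVector x, NumericVector mu,
                        NumericVector invstd, NumericVector gamma,
                        NumericVector beta) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector y = alloc4(H, W, C, N), xhat = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double* xs = x.begin() + off;
      double* hs = xhat.begin() + off;
      double* ys = y.begin() + off;
      const double m = mu[c], is = invstd[c], g = gamma[c], bt = beta[c];
      for (size_t p = 0; p < HW; ++p) {
        const double h = (xs[p] - m) * is;
        hs[p] = h;
        const double v = g * h + bt;
        ys[p] = v > 0 ? v : 0;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// Fused backward: masks dy by the ReLU gate (y > 0), accumulates
// per-channel dgamma/dbeta, then applies the batch-norm input
// gradient dx = gamma*invstd * (dy - dbeta/M - xhat * dgamma/M).
// [[Rcpp::export]]
List cpp_bnrelu_backward(NumericVector dy, NumericVector y,
                         NumericVector xhat, NumericVector gamma,
                         NumericVector invstd) {
  int H, W, C, N;
  get_dims4(dy, H, W, C, N);
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  NumericVector dgamma(C), dbeta(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double* ds = dy.begin() + off;
      const double* ys = y.begin() + off;
      const double* hs = xhat.begin() + off;
      double a = 0, b = 0;
      for (size_t p = 0; p < HW; ++p) {
        if (ys[p] > 0) { a += ds[p] * hs[p]; b += ds[p]; }
      }
      dgamma[c] += a; dbeta[c] += b;
    }
  }
  NumericVector dx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double* ds = dy.begin() + off;
      const double* ys = y.begin() + off;
      const double* hs = xhat.begin() + off;
      double* os = dx.begin() + off;
      const double gi = gamma[c] * invstd[c];
      const double mg = dgamma[c] / M, mb = dbeta[c] / M;
      for (size_t p = 0; p < HW; ++p) {
        const double d = ys[p] > 0 ? ds[p] : 0;
        os[p] = gi * (d - mb - hs[p] * mg);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// 2x2 max-pooling, stride 2, floor semantics on odd sizes. idx holds
// the 0-based linear position (h + H*w) of each retained maximum in
// its pre-pool plane.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Hp = H / 2, Wp = W / 2;
  if (Hp < 1 || Wp < 1) stop("input too small to pool");
  NumericVector y = alloc4(Hp, Wp, C, N);
  IntegerVector idx = alloc4i(Hp, Wp, C, N);
  const size_t HW = (size_t)H * W, HWp = (size_t)Hp * Wp;
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* xs = x.begin() + s * HW;
    double* ys = y.begin() + s * HWp;
    int* is = idx.begin() + s * HWp;
    for (int wp = 0; wp < Wp; ++wp) {
      for (int hp = 0; hp < Hp; ++hp) {
        const int h0 = 2 * hp, w0 = 2 * wp;
        int best = h0 + H * w0;
        double bv = xs[best];
        const int cand[3] = { h0 + 1 + H * w0, h0 + H * (w0 + 1),
                              h0 + 1 + H * (w0 + 1) };
        for (int k = 0; k < 3; ++k) {
          if (xs[cand[k]] > bv) { bv = xs[cand[k]]; best = cand[k]; }
        }
        ys[hp + Hp * wp] = bv;
        is[hp + Hp * wp] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Scatter values to recorded positions on an H x W grid (max-unpooling
// forward; also the backward pass of max-pooling). Unrecorded
// positions stay zero.
// [[Rcpp::export]]
NumericVector cpp_pool_scatter(NumericVector v, IntegerVector idx,
                               int H, int W) {
  int Hp, Wp, C, N;
  {
    IntegerVector d = v.attr("dim");
    Hp = d[0]; Wp = d[1]; C = d[2]; N = d[3];
  }
  NumericVector y = alloc4(H, W, C, N);
  const size_t HW = (size_t)H * W, HWp = (size_t)Hp * Wp;
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* vs = v.begin() + s * HWp;
    const int* is = idx.begin() + s * HWp;
    double* ys = y.begin() + s * HW;
    for (size_t p = 0; p < HWp; ++p) ys[is[p]] = vs[p];
  }
  return y;
}

// Gather from recorded positions (max-unpooling backward).
// [[Rcpp::export]]
NumericVector cpp_pool_gather(NumericVector g, IntegerVector idx) {
  int H, W, C, N;
  get_dims4(g, H, W, C, N);
  IntegerVector d = idx.attr("dim");
  const int Hp = d[0], Wp = d[1];
  NumericVector y = alloc4(Hp, Wp, C, N);
  const size_t HW = (size_t)H * W, HWp = (size_t)Hp * Wp;
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* gs = g.begin() + s * HW;
    const int* is = idx.begin() + s * HWp;
    double* ys = y.begin() + s * HWp;
    for (size_t p = 0; p < HWp; ++p) ys[p] = gs[is[p]];
  }
  return y;
}
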