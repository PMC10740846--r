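// Low-level convolution / pooling kernels for the CNN engine.
//
// Tensor layout convention (matching the R side): batched feature maps are
// R arrays with dim = c(N, C, H, W); R is column-major, so the linear index
// of element (n, c, h, w) (all 0-based) is n + N*(c + C*(h + H*w)).
// Convolution weights have dim = c(Cout, Cin, K, K).
//
// Convolution is im2col + GEMM.  The im2col matrix is stored transposed,
// Xt: (N*OH*OW) x (Cin*K*K), so that every fill/drain touches contiguous
// runs of N doubles in both source and destination (n is the fastest-moving
// index on both sides).  The forward pass can hand the im2col matrix back to
// R so the backward pass does not need to rebuild it.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void dims4(const NumericVector &x, int &a, int &b, int &c, int &d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  a = dm[0]; b = dm[1]; c = dm[2]; d = dm[3];
}

// fill Xt ((N*OH*OW) x (C*K*K)) from x ((N,C,H,W)); both sides contiguous in n
static void im2colT(const double *xp, int N, int C, int H, int W,
                    int K, int stride, int pad, int dil,
                    int OH, int OW, arma::mat &Xt) {
  Xt.zeros();
  const size_t nb = sizeof(double) * N;
  for (int kw = 0; kw < K; ++kw) {
    for (int kh = 0; kh < K; ++kh) {
      for (int ci = 0; ci < C; ++ci) {
        double *col = Xt.colptr(ci + C * (kh + K * kw));
        for (int ow = 0; ow < OW; ++ow) {
          const int iw = ow * stride - pad + kw * dil;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < OH; ++oh) {
            const int ih = oh * stride - pad + kh * dil;
            if (ih < 0 || ih >= H) continue;
            std::memcpy(col + static_cast<size_t>(N) * (oh + OH * ow),
                        xp + static_cast<size_t>(N) * (ci + C * (ih + H * iw)), nb);
          }
        }
      }
    }
  }
}

static void computeOut(int H, int W, int K, int stride, int pad, int dil,
                       int &OH, int &OW) {
  OH = (H + 2 * pad - dil * (K - 1) - 1) / stride + 1;
  OW = (W + 2 * pad - dil * (K - 1) - 1) / stride + 1;
  if (OH < 1 || OW < 1) stop("conv2d: output would be empty");
}

// [[Rcpp::export]]
List cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                    int stride, int pad, int dil, bool keepCols = false) {
  int N, C, H, W, Co, Ci, K1, K2;
  dims4(x, N, C, H, W);
  dims4(w, Co, Ci, K1, K2);
  if (Ci != C) stop("conv2d: input has %d channels, weights expect %d", C, Ci);
  if (K1 != K2) stop("conv2d: only square kernels are supported");
  const int K = K1;
  int OH, OW;
  computeOut(H, W, K, stride, pad, dil, OH, OW);
  const int R = C * K * K;
  const int Q = N * OH * OW;

  NumericMatrix xcol(Q, R);
  arma::mat Xt(xcol.begin(), Q, R, false, true);
  im2colT(x.begin(), N, C, H, W, K, stride, pad, dil, OH, OW, Xt);
  arma::mat Wm(const_cast<double *>(w.begin()), Co, R, false, true);
  arma::mat Yt = Xt * Wm.t();   // Q x Co

  NumericVector y(static_cast<R_xlen_t>(N) * Co * OH * OW);
  double *yp = y.begin();
  const size_t nb = sizeof(double) * N;
  for (int co = 0; co < Co; ++co) {
    const double *src = Yt.colptr(co);
    const double bc = b[co];
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        double *dst = yp + static_cast<size_t>(N) * (co + Co * (oh + OH * ow));
        std::memcpy(dst, src + static_cast<size_t>(N) * (oh + OH * ow), nb);
        for (int n = 0; n < N; ++n) dst[n] += bc;
      }
  }
  y.attr("dim") = IntegerVector::create(N, Co, OH, OW);
  if (keepCols) return List::create(_["y"] = y, _["xcol"] = xcol);
  return List::create(_["y"] = y);
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, int dil,
                    Nullable<NumericMatrix> xcolCache = R_NilValue) {
  int N, C, H, W, Co, Ci, K1, K2, Nd, Cod, OH, OW;
  dims4(x, N, C, H, W);
  dims4(w, Co, Ci, K1, K2);
  dims4(dy, Nd, Cod, OH, OW);
  if (Nd != N || Cod != Co) stop("conv2d backward: gradient shape mismatch");
  const int K = K1;
  const int R = C * K * K;
  const int Q = N * OH * OW;

  arma::mat Xt;
  NumericMatrix xcol;
  if (xcolCache.isNotNull()) {
    xcol = xcolCache.get();
    if (xcol.nrow() != Q || xcol.ncol() != R)
      stop("conv2d backward: cached im2col has wrong shape");
    new (&Xt) arma::mat(xcol.begin(), Q, R, false, true);
  } else {
    Xt.set_size(Q, R);
    im2colT(x.begin(), N, C, H, W, K, stride, pad, dil, OH, OW, Xt);
  }

  // gather dY into (Q x Co); contiguous in n on both sides
  arma::mat dYt(Q, Co);
  const double *dyp = dy.begin();
  const size_t nb = sizeof(double) * N;
  for (int co = 0; co < Co; ++co) {
    double *dst = dYt.colptr(co);
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh)
        std::memcpy(dst + static_cast<size_t>(N) * (oh + OH * ow),
                    dyp + static_cast<size_t>(N) * (co + Co * (oh + OH * ow)), nb);
  }

  arma::mat Wm(const_cast<double *>(w.begin()), Co, R, false, true);
  arma::mat dW = dYt.t() * Xt;          // Co x R, matches dim(w) memory layout
  arma::rowvec db = arma::sum(dYt, 0);
  arma::mat dXt = dYt * Wm;             // Q x R

  NumericVector dx(static_cast<R_xlen_t>(N) * C * H * W);
  double *dxp = dx.begin();
  for (int kw = 0; kw < K; ++kw) {
    for (int kh = 0; kh < K; ++kh) {
      for (int ci = 0; ci < C; ++ci) {
        const double *col = dXt.colptr(ci + C * (kh + K * kw));
        for (int ow = 0; ow < OW; ++ow) {
          const int iw = ow * stride - pad + kw * dil;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < OH; ++oh) {
            const int ih = oh * stride - pad + kh * dil;
            if (ih < 0 || ih >= H) continue;
            double *dst = dxp + static_cast<size_t>(N) * (ci + C * (ih + H * iw));
            const double *src = col + static_cast<size_t>(N) * (oh + OH * ow);
            for (int n = 0; n < N; ++n) dst[n] += src[n];
          }
        }
      }
    }
  }

  NumericVector dwv(dW.memptr(), dW.memptr() + dW.n_elem);
  dwv.attr("dim") = IntegerVector::create(Co, Ci, K1, K2);
  dx.attr("dim") = IntegerVector::create(N, C, H, W);
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Non-overlapping average pooling (kernel == stride).
// [[Rcpp::export]]
NumericVector cpp_avgpool_fwd(NumericVector x, int k) {
  int N, C, H, W;
  dims4(x, N, C, H, W);
  if (H % k != 0 || W % k != 0)
    stop("avgpool: spatial size (%d x %d) not divisible by kernel %d", H, W, k);
  const int OH = H / k, OW = W / k;
  NumericVector y(static_cast<R_xlen_t>(N) * C * OH * OW);
  const double *xp = x.begin();
  double *yp = y.begin();
  const double inv = 1.0 / (k * k);
  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double s = 0.0;
          for (int kw = 0; kw < k; ++kw)
            for (int kh = 0; kh < k; ++kh)
              s += xp[n + static_cast<size_t>(N) * (c + C * ((oh * k + kh) + H * (ow * k + kw)))];
          yp[n + static_cast<size_t>(N) * (c + C * (oh + OH * ow))] = s * inv;
        }
  y.attr("dim") = IntegerVector::create(N, C, OH, OW);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector dy, int k) {
  int N, C, OH, OW;
  dims4(dy, N, C, OH, OW);
  const int H = OH * k, W = OW * k;
  NumericVector dx(static_cast<R_xlen_t>(N) * C * H * W);
  const double *dyp = dy.begin();
  double *dxp = dx.begin();
  const double inv = 1.0 / (k * k);
  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          const double g = dyp[n + static_cast<size_t>(N) * (c + C * (oh + OH * ow))] * inv;
          for (int kw = 0; kw < k; ++kw)
            for (int kh = 0; kh < k; ++kh)
              dxp[n + static_cast<size_t>(N) * (c + C * ((oh * k + kh) + H * (ow * k + kw)))] = g;
        }
  dx.attr("dim") = IntegerVector::create(N, C, H, W);
  return dx;
}

// Max pooling with padding (used in the backbone stem: 3x3, stride 2, pad 1).
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  int N, C, H, W;
  dims4(x, N, C, H, W);
  const int OH = (H + 2 * pad - k) / stride + 1;
  const int OW = (W + 2 * pad - k) / stride + 1;
  NumericVector y(static_cast<R_xlen_t>(N) * C * OH * OW);
  IntegerVector arg(y.size());
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ap = arg.begin();
  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = R_NegInf;
          int bestIdx = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int iw = ow * stride - pad + kw;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int ih = oh * stride - pad + kh;
              if (ih < 0 || ih >= H) continue;
              const int idx = n + N * (c + C * (ih + H * iw));
              if (xp[idx] > best) { best = xp[idx]; bestIdx = idx; }
            }
          }
          const int o = n + N * (c + C * (oh + OH * ow));
          yp[o] = best;
          ap[o] = bestIdx;
        }
  y.attr("dim") = IntegerVector::create(N, C, OH, OW);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector argmax,
                              IntegerVector xdim) {
  NumericVector dx(static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3]);
  double *dxp = dx.begin();
  const double *dyp = dy.begin();
  const int *ap = argmax.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    if (ap[i] >= 0) dxp[ap[i]] += dyp[i];
  dx.attr("dim") = xdim;
  return dx;
}
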