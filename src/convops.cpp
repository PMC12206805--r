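// Numerical kernels for the CNN stack and mask utilities.
//
// Tensor layout is channel-first, column-major R arrays:
//   2-d feature maps: (C, H, W, N)   3-d feature maps: (C, D, H, W, N)
// so the C channel values of one voxel are contiguous, which lets im2col
// copy whole channel blocks. Convolutions are im2col + GEMM (BLAS dgemm via
// Armadillo); depthwise convolutions use direct tap loops (their FLOP share
// is negligible).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_len(int L, int k, int s, int p) {
  return (L + 2 * p - k) / s + 1;
}

// ---------------------------------------------------------------- conv2d --
//
// Kernels run in single precision internally (GEMM-bound; float halves
// both the arithmetic cost and the memory traffic). Inputs are padded
// into a per-sample buffer first so the im2col/col2im loops are
// branch-free block copies.

static void pad_sample2d(const double* xn, int C, int H, int W, int p,
                         std::vector<float>& xpad) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  std::fill(xpad.begin(), xpad.end(), 0.0f);
  for (int w = 0; w < W; ++w) {
    const double* src = xn + (size_t)C * H * w;
    float* dst = xpad.data() + (size_t)C * (p + (size_t)Hp * (w + p));
    for (int i = 0; i < C * H; ++i) dst[i] = (float)src[i];
  }
}

static void im2col2d(const double* x, int C, int H, int W, int N,
                     int k, int s, int p, arma::fmat& col) {
  const int OH = out_len(H, k, s, p), OW = out_len(W, k, s, p);
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  std::vector<float> xpad((size_t)C * Hp * Wp);
  for (int n = 0; n < N; ++n) {
    pad_sample2d(x + (size_t)n * C * H * W, C, H, W, p, xpad);
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        float* cm = col.colptr((size_t)oh + (size_t)OH * (ow + (size_t)OW * n));
        for (int kw = 0; kw < k; ++kw)
          for (int kh = 0; kh < k; ++kh) {
            const float* src = xpad.data() +
              (size_t)C * ((oh * s + kh) + (size_t)Hp * (ow * s + kw));
            float* dst = cm + (size_t)C * (kh + k * kw);
            for (int c = 0; c < C; ++c) dst[c] = src[c];
          }
      }
  }
}

static void col2im2d(const arma::fmat& col, int C, int H, int W, int N,
                     int k, int s, int p, double* gx) {
  const int OH = out_len(H, k, s, p), OW = out_len(W, k, s, p);
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  std::vector<float> gpad((size_t)C * Hp * Wp);
  for (int n = 0; n < N; ++n) {
    std::fill(gpad.begin(), gpad.end(), 0.0f);
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        const float* cm =
          col.colptr((size_t)oh + (size_t)OH * (ow + (size_t)OW * n));
        for (int kw = 0; kw < k; ++kw)
          for (int kh = 0; kh < k; ++kh) {
            float* dst = gpad.data() +
              (size_t)C * ((oh * s + kh) + (size_t)Hp * (ow * s + kw));
            const float* src = cm + (size_t)C * (kh + k * kw);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
      }
    double* gn = gx + (size_t)n * C * H * W;
    for (int w = 0; w < W; ++w) {
      const float* src = gpad.data() +
        (size_t)C * (p + (size_t)Hp * (w + p));
      double* dst = gn + (size_t)C * H * w;
      for (int i = 0; i < C * H; ++i) dst[i] = src[i];
    }
  }
}

static arma::fmat to_fmat(const NumericMatrix& w) {
  arma::fmat out(w.nrow(), w.ncol());
  std::copy(w.begin(), w.end(), out.memptr());
  return out;
}

static arma::fmat to_fmat_vec(const NumericVector& v, int nrow) {
  arma::fmat out(nrow, v.size() / nrow);
  std::copy(REAL(v), REAL(v) + v.size(), out.memptr());
  return out;
}

// w: (C_in * k * k) x C_out, row order c + C_in * (kh + k * kw).
// When `keep_col` the im2col matrix is returned as an external pointer so
// the backward pass can reuse it.
// [[Rcpp::export]]
List cpp_conv2d_fw(NumericVector x, IntegerVector dims,
                   NumericMatrix w, int k, int s, int p,
                   bool keep_col = false) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int OH = out_len(H, k, s, p), OW = out_len(W, k, s, p);
  const int Cout = w.ncol();
  arma::fmat* col = new arma::fmat((size_t)C * k * k, (size_t)OH * OW * N);
  if (k == 1 && s == 1 && p == 0) {
    std::copy(REAL(x), REAL(x) + col->n_elem, col->memptr());
  } else {
    im2col2d(REAL(x), C, H, W, N, k, s, p, *col);
  }
  arma::fmat y = to_fmat(w).t() * (*col);  // C_out x M
  NumericVector out(y.n_elem);
  std::copy(y.memptr(), y.memptr() + y.n_elem, REAL(out));
  out.attr("dim") = IntegerVector::create(Cout, OH, OW, N);
  if (keep_col) {
    XPtr<arma::fmat> ptr(col, true);
    return List::create(_["y"] = out, _["col"] = ptr);
  }
  delete col;
  return List::create(_["y"] = out);
}

// [[Rcpp::export]]
List cpp_conv2d_bw(SEXP colptr, IntegerVector dims, NumericMatrix w,
                   NumericVector gy, int k, int s, int p,
                   bool need_gx = true) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Cout = w.ncol();
  XPtr<arma::fmat> col(colptr);
  arma::fmat gym = to_fmat_vec(gy, Cout);
  arma::fmat gw = (*col) * gym.t();                    // K x C_out
  NumericMatrix gwm(gw.n_rows, gw.n_cols);
  std::copy(gw.memptr(), gw.memptr() + gw.n_elem, gwm.begin());
  if (!need_gx) return List::create(_["gw"] = gwm);
  arma::fmat gcol = to_fmat(w) * gym;                  // K x M
  NumericVector gx((size_t)C * H * W * N);
  if (k == 1 && s == 1 && p == 0) {
    std::copy(gcol.memptr(), gcol.memptr() + gcol.n_elem, REAL(gx));
  } else {
    col2im2d(gcol, C, H, W, N, k, s, p, REAL(gx));
  }
  gx.attr("dim") = dims;
  return List::create(_["gx"] = gx, _["gw"] = gwm);
}

// ---------------------------------------------------------------- conv3d --

template <typename T>
static void pad_sample3d(const T* xn, int C, int D, int H, int W,
                         int p, std::vector<float>& xpad) {
  const int Dp = D + 2 * p, Hp = H + 2 * p;
  std::fill(xpad.begin(), xpad.end(), 0.0f);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      const T* src = xn + (size_t)C * D * (h + (size_t)H * w);
      float* dst = xpad.data() +
        (size_t)C * (p + (size_t)Dp * ((h + p) + (size_t)Hp * (w + p)));
      for (int i = 0; i < C * D; ++i) dst[i] = (float)src[i];
    }
}

template <typename T>
static void im2col3d(const T* x, int C, int D, int H, int W, int N,
                     int k, int sd, int sh, int sw, int p,
                     arma::fmat& col) {
  const int OD = out_len(D, k, sd, p), OH = out_len(H, k, sh, p),
            OW = out_len(W, k, sw, p);
  const int Dp = D + 2 * p, Hp = H + 2 * p, Wp = W + 2 * p;
  std::vector<float> xpad((size_t)C * Dp * Hp * Wp);
  for (int n = 0; n < N; ++n) {
    pad_sample3d(x + (size_t)n * C * D * H * W, C, D, H, W, p, xpad);
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh)
        for (int od = 0; od < OD; ++od) {
          float* cm = col.colptr((size_t)od +
            (size_t)OD * (oh + (size_t)OH * (ow + (size_t)OW * n)));
          const size_t base = (size_t)C * ((od * sd) +
            (size_t)Dp * ((oh * sh) + (size_t)Hp * (ow * sw)));
          for (int kw = 0; kw < k; ++kw)
            for (int kh = 0; kh < k; ++kh) {
              const float* src = xpad.data() + base +
                (size_t)C * ((size_t)Dp * (kh + (size_t)Hp * kw));
              float* dst = cm + (size_t)C * k * (kh + k * kw);
              // kd runs over contiguous C-blocks in both src and dst
              const int run = C * k;
              for (int i = 0; i < run; ++i) dst[i] = src[i];
            }
        }
  }
}

template <typename T>
static void col2im3d(const arma::fmat& col, int C, int D, int H, int W,
                     int N, int k, int sd, int sh, int sw, int p,
                     T* gx) {
  const int OD = out_len(D, k, sd, p), OH = out_len(H, k, sh, p),
            OW = out_len(W, k, sw, p);
  const int Dp = D + 2 * p, Hp = H + 2 * p, Wp = W + 2 * p;
  std::vector<float> gpad((size_t)C * Dp * Hp * Wp);
  for (int n = 0; n < N; ++n) {
    std::fill(gpad.begin(), gpad.end(), 0.0f);
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh)
        for (int od = 0; od < OD; ++od) {
          const float* cm = col.colptr((size_t)od +
            (size_t)OD * (oh + (size_t)OH * (ow + (size_t)OW * n)));
          const size_t base = (size_t)C * ((od * sd) +
            (size_t)Dp * ((oh * sh) + (size_t)Hp * (ow * sw)));
          for (int kw = 0; kw < k; ++kw)
            for (int kh = 0; kh < k; ++kh) {
              float* dst = gpad.data() + base +
                (size_t)C * ((size_t)Dp * (kh + (size_t)Hp * kw));
              const float* src = cm + (size_t)C * k * (kh + k * kw);
              const int run = C * k;
              for (int i = 0; i < run; ++i) dst[i] += src[i];
            }
        }
    T* gn = gx + (size_t)n * C * D * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const float* src = gpad.data() +
          (size_t)C * (p + (size_t)Dp * ((h + p) + (size_t)Hp * (w + p)));
        T* dst = gn + (size_t)C * D * (h + (size_t)H * w);
        for (int i = 0; i < C * D; ++i) dst[i] = (T)src[i];
      }
  }
}

// w: (C_in * k^3) x C_out, row order c + C_in * (kd + k * (kh + k * kw))
// [[Rcpp::export]]
List cpp_conv3d_fw(NumericVector x, IntegerVector dims,
                   NumericMatrix w, int k, IntegerVector stride, int p,
                   bool keep_col = false) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3], N = dims[4];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int OD = out_len(D, k, sd, p), OH = out_len(H, k, sh, p),
            OW = out_len(W, k, sw, p);
  const int Cout = w.ncol();
  arma::fmat* col = new arma::fmat((size_t)C * k * k * k,
                                   (size_t)OD * OH * OW * N);
  im2col3d(REAL(x), C, D, H, W, N, k, sd, sh, sw, p, *col);
  arma::fmat y = to_fmat(w).t() * (*col);
  NumericVector out(y.n_elem);
  std::copy(y.memptr(), y.memptr() + y.n_elem, REAL(out));
  out.attr("dim") = IntegerVector::create(Cout, OD, OH, OW, N);
  if (keep_col) {
    XPtr<arma::fmat> ptr(col, true);
    return List::create(_["y"] = out, _["col"] = ptr);
  }
  delete col;
  return List::create(_["y"] = out);
}

// [[Rcpp::export]]
List cpp_conv3d_bw(SEXP colptr, IntegerVector dims, NumericMatrix w,
                   NumericVector gy, int k, IntegerVector stride, int p,
                   bool need_gx = true) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3], N = dims[4];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int Cout = w.ncol();
  XPtr<arma::fmat> col(colptr);
  arma::fmat gym = to_fmat_vec(gy, Cout);
  arma::fmat gw = (*col) * gym.t();
  NumericMatrix gwm(gw.n_rows, gw.n_cols);
  std::copy(gw.memptr(), gw.memptr() + gw.n_elem, gwm.begin());
  if (!need_gx) return List::create(_["gw"] = gwm);
  arma::fmat gcol = to_fmat(w) * gym;
  NumericVector gx((size_t)C * D * H * W * N);
  col2im3d(gcol, C, D, H, W, N, k, sd, sh, sw, p, REAL(gx));
  gx.attr("dim") = dims;
  return List::create(_["gx"] = gx, _["gw"] = gwm);
}

// ------------------------------------------------------------------ relu --

// [[Rcpp::export]]
NumericVector cpp_relu_fw(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// gx = gy where the forward output was positive (y > 0 <=> x > 0).
// [[Rcpp::export]]
NumericVector cpp_relu_bw(NumericVector y, NumericVector gy) {
  NumericVector gx(gy.size());
  const double* yp = REAL(y);
  const double* gp = REAL(gy);
  double* op = REAL(gx);
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = yp[i] > 0 ? gp[i] : 0.0;
  gx.attr("dim") = gy.attr("dim");
  return gx;
}

// ------------------------------------------------------------- depthwise --

// w: C x (k * k), tap order kh + k * kw
// [[Rcpp::export]]
NumericVector cpp_dwconv2d_fw(NumericVector x, IntegerVector dims,
                              NumericMatrix w, int k, int s, int p) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int OH = out_len(H, k, s, p), OW = out_len(W, k, s, p);
  NumericVector out((size_t)C * OH * OW * N);
  std::fill(REAL(out), REAL(out) + out.size(), 0.0);
  const double* xp = REAL(x);
  double* yp = REAL(out);
  const double* wp = w.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * C * H * W;
    double* yn = yp + (size_t)n * C * OH * OW;
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        double* yv = yn + (size_t)C * (oh + (size_t)OH * ow);
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * s - p + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * s - p + kh;
            if (ih < 0 || ih >= H) continue;
            const double* xv = xn + (size_t)C * (ih + (size_t)H * iw);
            const double* wv = wp + (size_t)C * (kh + k * kw);
            for (int c = 0; c < C; ++c) yv[c] += wv[c] * xv[c];
          }
        }
      }
  }
  out.attr("dim") = IntegerVector::create(C, OH, OW, N);
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv2d_bw(NumericVector x, IntegerVector dims, NumericMatrix w,
                     NumericVector gy, int k, int s, int p) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int OH = out_len(H, k, s, p), OW = out_len(W, k, s, p);
  NumericVector gx((size_t)C * H * W * N);
  std::fill(REAL(gx), REAL(gx) + gx.size(), 0.0);
  NumericMatrix gw(C, k * k);
  const double* xp = REAL(x);
  const double* gp = REAL(gy);
  const double* wp = w.begin();
  double* gxp = REAL(gx);
  double* gwp = gw.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * C * H * W;
    const double* gn = gp + (size_t)n * C * OH * OW;
    double* gxn = gxp + (size_t)n * C * H * W;
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        const double* gv = gn + (size_t)C * (oh + (size_t)OH * ow);
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * s - p + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * s - p + kh;
            if (ih < 0 || ih >= H) continue;
            const double* xv = xn + (size_t)C * (ih + (size_t)H * iw);
            double* gxv = gxn + (size_t)C * (ih + (size_t)H * iw);
            const double* wv = wp + (size_t)C * (kh + k * kw);
            double* gwv = gwp + (size_t)C * (kh + k * kw);
            for (int c = 0; c < C; ++c) {
              gxv[c] += wv[c] * gv[c];
              gwv[c] += xv[c] * gv[c];
            }
          }
        }
      }
  }
  gx.attr("dim") = dims;
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// w: C x (k^3), tap order kd + k * (kh + k * kw)
// [[Rcpp::export]]
NumericVector cpp_dwconv3d_fw(NumericVector x, IntegerVector dims,
                              NumericMatrix w, int k, IntegerVector stride,
                              int p) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3], N = dims[4];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int OD = out_len(D, k, sd, p), OH = out_len(H, k, sh, p),
            OW = out_len(W, k, sw, p);
  NumericVector out((size_t)C * OD * OH * OW * N);
  std::fill(REAL(out), REAL(out) + out.size(), 0.0);
  const double* xp = REAL(x);
  double* yp = REAL(out);
  const double* wp = w.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * C * D * H * W;
    double* yn = yp + (size_t)n * C * OD * OH * OW;
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh)
        for (int od = 0; od < OD; ++od) {
          double* yv = yn + (size_t)C * (od + (size_t)OD * (oh + (size_t)OH * ow));
          for (int kw = 0; kw < k; ++kw) {
            const int iw = ow * sw - p + kw;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int ih = oh * sh - p + kh;
              if (ih < 0 || ih >= H) continue;
              for (int kd = 0; kd < k; ++kd) {
                const int id = od * sd - p + kd;
                if (id < 0 || id >= D) continue;
                const double* xv =
                  xn + (size_t)C * (id + (size_t)D * (ih + (size_t)H * iw));
                const double* wv = wp + (size_t)C * (kd + k * (kh + k * kw));
                for (int c = 0; c < C; ++c) yv[c] += wv[c] * xv[c];
              }
            }
          }
        }
  }
  out.attr("dim") = IntegerVector::create(C, OD, OH, OW, N);
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv3d_bw(NumericVector x, IntegerVector dims, NumericMatrix w,
                     NumericVector gy, int k, IntegerVector stride, int p) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3], N = dims[4];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int OD = out_len(D, k, sd, p), OH = out_len(H, k, sh, p),
            OW = out_len(W, k, sw, p);
  NumericVector gx((size_t)C * D * H * W * N);
  std::fill(REAL(gx), REAL(gx) + gx.size(), 0.0);
  NumericMatrix gw(C, k * k * k);
  const double* xp = REAL(x);
  const double* gp = REAL(gy);
  const double* wp = w.begin();
  double* gxp = REAL(gx);
  double* gwp = gw.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * C * D * H * W;
    const double* gn = gp + (size_t)n * C * OD * OH * OW;
    double* gxn = gxp + (size_t)n * C * D * H * W;
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh)
        for (int od = 0; od < OD; ++od) {
          const double* gv =
            gn + (size_t)C * (od + (size_t)OD * (oh + (size_t)OH * ow));
          for (int kw = 0; kw < k; ++kw) {
            const int iw = ow * sw - p + kw;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int ih = oh * sh - p + kh;
              if (ih < 0 || ih >= H) continue;
              for (int kd = 0; kd < k; ++kd) {
                const int id = od * sd - p + kd;
                if (id < 0 || id >= D) continue;
                const size_t off =
                  (size_t)C * (id + (size_t)D * (ih + (size_t)H * iw));
                const double* xv = xn + off;
                double* gxv = gxn + off;
                const double* wv = wp + (size_t)C * (kd + k * (kh + k * kw));
                double* gwv = gwp + (size_t)C * (kd + k * (kh + k * kw));
                for (int c = 0; c < C; ++c) {
                  gxv[c] += wv[c] * gv[c];
                  gwv[c] += xv[c] * gv[c];
                }
              }
            }
          }
        }
  }
  gx.attr("dim") = dims;
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// ------------------------------------------------------------- batchnorm --

// x viewed as C x M (channel-first); training-mode forward.
// [[Rcpp::export]]
List cpp_bn_fw(NumericVector x, int C, NumericVector gamma,
               NumericVector beta, double eps) {
  const size_t M = x.size() / C;
  NumericVector y(x.size());
  NumericVector mean(C), var(C);
  const double* xp = REAL(x);
  double* mp = REAL(mean);
  double* vp = REAL(var);
  for (size_t m = 0; m < M; ++m) {
    const double* xv = xp + m * C;
    for (int c = 0; c < C; ++c) mp[c] += xv[c];
  }
  for (int c = 0; c < C; ++c) mp[c] /= (double)M;
  for (size_t m = 0; m < M; ++m) {
    const double* xv = xp + m * C;
    for (int c = 0; c < C; ++c) {
      const double d = xv[c] - mp[c];
      vp[c] += d * d;
    }
  }
  NumericVector invstd(C);
  for (int c = 0; c < C; ++c) {
    vp[c] /= (double)M;
    REAL(invstd)[c] = 1.0 / std::sqrt(vp[c] + eps);
  }
  double* yp = REAL(y);
  const double* gp = REAL(gamma);
  const double* bp = REAL(beta);
  const double* ip = REAL(invstd);
  for (size_t m = 0; m < M; ++m) {
    const double* xv = xp + m * C;
    double* yv = yp + m * C;
    for (int c = 0; c < C; ++c)
      yv[c] = gp[c] * (xv[c] - mp[c]) * ip[c] + bp[c];
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var,
                      _["invstd"] = invstd);
}

// Inference-mode forward with running statistics.
// [[Rcpp::export]]
NumericVector cpp_bn_fw_eval(NumericVector x, int C, NumericVector gamma,
                             NumericVector beta, NumericVector rmean,
                             NumericVector rvar, double eps) {
  const size_t M = x.size() / C;
  NumericVector y(x.size());
  std::vector<double> sc(C), sh(C);
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(REAL(rvar)[c] + eps);
    sc[c] = REAL(gamma)[c] * is;
    sh[c] = REAL(beta)[c] - sc[c] * REAL(rmean)[c];
  }
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (size_t m = 0; m < M; ++m) {
    const double* xv = xp + m * C;
    double* yv = yp + m * C;
    for (int c = 0; c < C; ++c) yv[c] = sc[c] * xv[c] + sh[c];
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bw(NumericVector x, int C, NumericVector gy, NumericVector gamma,
               NumericVector mean, NumericVector invstd) {
  const size_t M = x.size() / C;
  NumericVector gx(x.size());
  NumericVector ggamma(C), gbeta(C);
  const double* xp = REAL(x);
  const double* gp = REAL(gy);
  const double* mp = REAL(mean);
  const double* ip = REAL(invstd);
  double* ggp = REAL(ggamma);
  double* gbp = REAL(gbeta);
  for (size_t m = 0; m < M; ++m) {
    const double* xv = xp + m * C;
    const double* gv = gp + m * C;
    for (int c = 0; c < C; ++c) {
      gbp[c] += gv[c];
      ggp[c] += gv[c] * (xv[c] - mp[c]) * ip[c];
    }
  }
  double* gxp = REAL(gx);
  const double* gam = REAL(gamma);
  const double invM = 1.0 / (double)M;
  for (size_t m = 0; m < M; ++m) {
    const double* xv = xp + m * C;
    const double* gv = gp + m * C;
    double* gxv = gxp + m * C;
    for (int c = 0; c < C; ++c) {
      const double xhat = (xv[c] - mp[c]) * ip[c];
      gxv[c] = gam[c] * ip[c] *
        (gv[c] - invM * gbp[c] - xhat * invM * ggp[c]);
    }
  }
  gx.attr("dim") = x.attr("dim");
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}

// --------------------------------------------------------------- maxpool --

// 2-d max pooling, kernel k, stride s, pad p; returns argmax for backward.
// [[Rcpp::export]]
List cpp_maxpool2d_fw(NumericVector x, IntegerVector dims, int k, int s,
                      int p) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int OH = out_len(H, k, s, p), OW = out_len(W, k, s, p);
  NumericVector y((size_t)C * OH * OW * N);
  IntegerVector arg(y.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ap = INTEGER(arg);
  for (int n = 0; n < N; ++n) {
    const size_t xoff = (size_t)n * C * H * W;
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        const size_t yo = (size_t)C * (oh + (size_t)OH * (ow + (size_t)OW * n));
        for (int c = 0; c < C; ++c) {
          double best = -INFINITY; size_t bidx = 0;
          for (int kw = 0; kw < k; ++kw) {
            const int iw = ow * s - p + kw;
            if (iw < 0 || iw >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int ih = oh * s - p + kh;
              if (ih < 0 || ih >= H) continue;
              const size_t ix = xoff + c + (size_t)C * (ih + (size_t)H * iw);
              if (xp[ix] > best) { best = xp[ix]; bidx = ix; }
            }
          }
          yp[yo + c] = best;
          ap[yo + c] = (int)bidx;
        }
      }
  }
  y.attr("dim") = IntegerVector::create(C, OH, OW, N);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector gy, IntegerVector argmax,
                             int n_in) {
  NumericVector gx(n_in);
  std::fill(REAL(gx), REAL(gx) + n_in, 0.0);
  const double* gp = REAL(gy);
  const int* ap = INTEGER(argmax);
  for (R_xlen_t i = 0; i < gy.size(); ++i) REAL(gx)[ap[i]] += gp[i];
  return gx;
}

// 3-d max pooling, cubic kernel k, per-axis strides.
// [[Rcpp::export]]
List cpp_maxpool3d_fw(NumericVector x, IntegerVector dims, int k,
                      IntegerVector stride, int p) {
  const int C = dims[0], D = dims[1], H = dims[2], W = dims[3], N = dims[4];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int OD = out_len(D, k, sd, p), OH = out_len(H, k, sh, p),
            OW = out_len(W, k, sw, p);
  NumericVector y((size_t)C * OD * OH * OW * N);
  IntegerVector arg(y.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ap = INTEGER(arg);
  for (int n = 0; n < N; ++n) {
    const size_t xoff = (size_t)n * C * D * H * W;
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh)
        for (int od = 0; od < OD; ++od) {
          const size_t yo = (size_t)C *
            (od + (size_t)OD * (oh + (size_t)OH * (ow + (size_t)OW * n)));
          for (int c = 0; c < C; ++c) {
            double best = -INFINITY; size_t bidx = 0;
            for (int kw = 0; kw < k; ++kw) {
              const int iw = ow * sw - p + kw;
              if (iw < 0 || iw >= W) continue;
              for (int kh = 0; kh < k; ++kh) {
                const int ih = oh * sh - p + kh;
                if (ih < 0 || ih >= H) continue;
                for (int kd = 0; kd < k; ++kd) {
                  const int id = od * sd - p + kd;
                  if (id < 0 || id >= D) continue;
                  const size_t ix = xoff + c +
                    (size_t)C * (id + (size_t)D * (ih + (size_t)H * iw));
                  if (xp[ix] > best) { best = xp[ix]; bidx = ix; }
                }
              }
            }
            yp[yo + c] = best;
            ap[yo + c] = (int)bidx;
          }
        }
  }
  y.attr("dim") = IntegerVector::create(C, OD, OH, OW, N);
  return List::create(_["y"] = y, _["argmax"] = arg);
}


// ------------------------------------------------------- fused 3-d stem --
//
// conv3d(1->c1, k3 s2) + BN + ReLU + conv3d(c1->c2, k3 s2) + BN + ReLU +
// adaptive spectral pool to depth `out_d` + channel/depth merge, executed
// entirely in single precision with cached im2col matrices. This is the
// dominant compute block of the hybrid network; fusing it avoids
// round-tripping the large stem activations through R.

struct StemCache {
  arma::fmat col1, col2;  // im2col matrices
  arma::fmat z1, z2;      // pre-BN conv outputs (c x M views)
  arma::fmat a1, a2;      // post-ReLU scratch
  arma::fvec m1, is1, m2, is2;  // batch means / inverse stds
  int D1, H1, W1, D2, H2, W2, N, out_d;
};

static void bn_stats_f(const arma::fmat& z, arma::fvec& mean,
                       arma::fvec& invstd, float eps) {
  mean = arma::mean(z, 1);
  arma::fvec var = arma::var(z, 1 /* population */, 1);
  invstd = 1.0f / arma::sqrt(var + eps);
}

// [[Rcpp::export]]
List cpp_stem3d_fw(NumericVector x, IntegerVector dims,
                   NumericMatrix w1, NumericVector g1, NumericVector b1,
                   NumericVector rm1, NumericVector rv1,
                   NumericMatrix w2, NumericVector g2, NumericVector b2,
                   NumericVector rm2, NumericVector rv2,
                   int out_d, double eps, bool training,
                   SEXP prev = R_NilValue) {
  const int D = dims[1], H = dims[2], W = dims[3], N = dims[4];
  const int c1 = w1.ncol(), c2 = w2.ncol();
  const int D1 = out_len(D, 3, 2, 1), H1 = out_len(H, 3, 2, 1),
            W1 = out_len(W, 3, 2, 1);
  const int D2 = out_len(D1, 3, 2, 1), H2 = out_len(H1, 3, 2, 1),
            W2 = out_len(W1, 3, 2, 1);
  const size_t M1 = (size_t)D1 * H1 * W1 * N;
  const size_t M2 = (size_t)D2 * H2 * W2 * N;

  // The cache is reused across calls (buffers keep their allocation).
  XPtr<StemCache> xp = Rf_isNull(prev)
    ? XPtr<StemCache>(new StemCache(), true) : XPtr<StemCache>(prev);
  StemCache& cc = *xp;
  cc.D1 = D1; cc.H1 = H1; cc.W1 = W1;
  cc.D2 = D2; cc.H2 = H2; cc.W2 = W2;
  cc.N = N; cc.out_d = out_d;

  cc.col1.set_size(27, M1);
  im2col3d(REAL(x), 1, D, H, W, N, 3, 2, 2, 2, 1, cc.col1);
  arma::fmat& z1 = cc.z1;
  z1 = to_fmat(w1).t() * cc.col1;  // c1 x M1
  arma::fvec sc1(c1), sh1(c1);
  if (training) {
    bn_stats_f(z1, cc.m1, cc.is1, (float)eps);
    for (int c = 0; c < c1; ++c) {
      sc1[c] = (float)REAL(g1)[c] * cc.is1[c];
      sh1[c] = -cc.m1[c] * sc1[c] + (float)REAL(b1)[c];
    }
  } else {
    for (int c = 0; c < c1; ++c) {
      const float is = 1.0f / std::sqrt((float)REAL(rv1)[c] + (float)eps);
      sc1[c] = (float)REAL(g1)[c] * is;
      sh1[c] = (float)REAL(b1)[c] - (float)REAL(rm1)[c] * sc1[c];
    }
  }
  arma::fmat& a1 = cc.a1;
  a1.set_size(c1, M1);
  for (size_t m = 0; m < M1; ++m) {
    const float* zv = z1.colptr(m);
    float* av = a1.colptr(m);
    for (int c = 0; c < c1; ++c) {
      const float v = sc1[c] * zv[c] + sh1[c];
      av[c] = v > 0 ? v : 0;
    }
  }
  cc.col2.set_size((size_t)c1 * 27, M2);
  im2col3d(a1.memptr(), c1, D1, H1, W1, N, 3, 2, 2, 2, 1, cc.col2);
  arma::fmat& z2 = cc.z2;
  z2 = to_fmat(w2).t() * cc.col2;  // c2 x M2
  arma::fvec sc2(c2), sh2(c2);
  if (training) {
    bn_stats_f(z2, cc.m2, cc.is2, (float)eps);
    for (int c = 0; c < c2; ++c) {
      sc2[c] = (float)REAL(g2)[c] * cc.is2[c];
      sh2[c] = -cc.m2[c] * sc2[c] + (float)REAL(b2)[c];
    }
  } else {
    for (int c = 0; c < c2; ++c) {
      const float is = 1.0f / std::sqrt((float)REAL(rv2)[c] + (float)eps);
      sc2[c] = (float)REAL(g2)[c] * is;
      sh2[c] = (float)REAL(b2)[c] - (float)REAL(rm2)[c] * sc2[c];
    }
  }
  arma::fmat& a2 = cc.a2;
  a2.set_size(c2, M2);
  for (size_t m = 0; m < M2; ++m) {
    const float* zv = z2.colptr(m);
    float* av = a2.colptr(m);
    for (int c = 0; c < c2; ++c) {
      const float v = sc2[c] * zv[c] + sh2[c];
      av[c] = v > 0 ? v : 0;
    }
  }

  // adaptive spectral pool to out_d, then merge (c2, out_d) -> channels
  NumericVector y((size_t)c2 * out_d * H2 * W2 * N);
  double* yp = REAL(y);
  const float* ap = a2.memptr();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h) {
        const size_t spat = h + (size_t)H2 * (w + (size_t)W2 * n);
        const float* acol = ap + (size_t)c2 * D2 * spat;
        double* ycol = yp + (size_t)c2 * out_d * spat;
        for (int i = 0; i < out_d; ++i) {
          const int d0 = (i * D2) / out_d;
          const int d1 = ((i + 1) * D2 + out_d - 1) / out_d;
          for (int c = 0; c < c2; ++c) {
            float acc = 0;
            for (int d = d0; d < d1; ++d) acc += acol[c + (size_t)c2 * d];
            ycol[c + (size_t)c2 * i] = acc / (d1 - d0);
          }
        }
      }
  y.attr("dim") = IntegerVector::create(c2 * out_d, H2, W2, N);

  List out;
  if (training) {
    // batch mean / variance (population) for running-stat updates in R
    NumericVector bm1(c1), bv1(c1), bm2(c2), bv2(c2);
    for (int c = 0; c < c1; ++c) {
      bm1[c] = cc.m1[c];
      bv1[c] = 1.0 / ((double)cc.is1[c] * cc.is1[c]) - eps;
    }
    for (int c = 0; c < c2; ++c) {
      bm2[c] = cc.m2[c];
      bv2[c] = 1.0 / ((double)cc.is2[c] * cc.is2[c]) - eps;
    }
    out = List::create(_["y"] = y, _["cache"] = xp,
                       _["bm1"] = bm1, _["bv1"] = bv1,
                       _["bm2"] = bm2, _["bv2"] = bv2);
  } else {
    out = List::create(_["y"] = y, _["cache"] = xp);
  }
  return out;
}

// Fused ReLU + BN backward on c x M float views, in place: `ga` enters as
// the gradient w.r.t. the post-ReLU activation and leaves as the gradient
// w.r.t. the pre-BN conv output. `z` is the cached pre-BN value, from
// which both the ReLU mask (gamma*xhat+beta > 0) and xhat are recomputed.
static void bn_bw_f(arma::fmat& ga, const arma::fmat& z,
                    const arma::fvec& mean, const arma::fvec& invstd,
                    const NumericVector& gamma, const NumericVector& beta,
                    arma::fvec& ggamma, arma::fvec& gbeta) {
  const int C = ga.n_rows;
  const size_t M = ga.n_cols;
  ggamma.zeros(C);
  gbeta.zeros(C);
  std::vector<float> gam(C), bet(C);
  for (int c = 0; c < C; ++c) {
    gam[c] = (float)REAL(gamma)[c];
    bet[c] = (float)REAL(beta)[c];
  }
  for (size_t m = 0; m < M; ++m) {
    float* gv = ga.colptr(m);
    const float* zv = z.colptr(m);
    for (int c = 0; c < C; ++c) {
      const float xhat = (zv[c] - mean[c]) * invstd[c];
      if (gam[c] * xhat + bet[c] > 0) {
        gbeta[c] += gv[c];
        ggamma[c] += gv[c] * xhat;
      } else {
        gv[c] = 0;
      }
    }
  }
  const float invM = 1.0f / (float)M;
  const float gb_[1] = {0};
  (void)gb_;
  for (size_t m = 0; m < M; ++m) {
    float* gv = ga.colptr(m);
    const float* zv = z.colptr(m);
    for (int c = 0; c < C; ++c) {
      const float xhat = (zv[c] - mean[c]) * invstd[c];
      gv[c] = gam[c] * invstd[c] *
        (gv[c] - invM * (float)gbeta[c] - xhat * invM * (float)ggamma[c]);
    }
  }
}

// [[Rcpp::export]]
List cpp_stem3d_bw(SEXP cacheptr, NumericVector gy,
                   NumericMatrix w1, NumericVector g1, NumericVector b1,
                   NumericMatrix w2, NumericVector g2, NumericVector b2) {
  XPtr<StemCache> cc(cacheptr);
  const int c1 = w1.ncol(), c2 = w2.ncol();
  const int D2 = cc->D2, H2 = cc->H2, W2 = cc->W2, N = cc->N;
  const int out_d = cc->out_d;
  const size_t M2 = (size_t)D2 * H2 * W2 * N;

  // un-merge + un-pool gy into ga2 (c2 x M2); reuse the a2 scratch (its
  // forward contents are no longer needed once z2 is available)
  arma::fmat& ga2 = cc->a2;
  ga2.zeros();
  const double* gp = REAL(gy);
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h) {
        const size_t spat = h + (size_t)H2 * (w + (size_t)W2 * n);
        const double* gcol_ = gp + (size_t)c2 * out_d * spat;
        float* acol = ga2.memptr() + (size_t)c2 * D2 * spat;
        for (int i = 0; i < out_d; ++i) {
          const int d0 = (i * D2) / out_d;
          const int d1 = ((i + 1) * D2 + out_d - 1) / out_d;
          const float inv = 1.0f / (d1 - d0);
          for (int c = 0; c < c2; ++c) {
            const float g = (float)gcol_[c + (size_t)c2 * i] * inv;
            for (int d = d0; d < d1; ++d) acol[c + (size_t)c2 * d] += g;
          }
        }
      }

  arma::fvec gg2, gb2v;
  bn_bw_f(ga2, cc->z2, cc->m2, cc->is2, g2, b2, gg2, gb2v);
  arma::fmat gw2 = cc->col2 * ga2.t();      // (c1*27) x c2
  arma::fmat gcol2 = to_fmat(w2) * ga2;     // (c1*27) x M2

  // col2im back to the first stage activation gradient (c1 x M1),
  // reusing the a1 scratch
  const size_t M1 = (size_t)cc->D1 * cc->H1 * cc->W1 * N;
  arma::fmat& ga1 = cc->a1;
  ga1.set_size(c1, M1);
  col2im3d(gcol2, c1, cc->D1, cc->H1, cc->W1, N, 3, 2, 2, 2, 1,
           ga1.memptr());
  gcol2.reset();

  arma::fvec gg1, gb1v;
  bn_bw_f(ga1, cc->z1, cc->m1, cc->is1, g1, b1, gg1, gb1v);
  arma::fmat gw1 = cc->col1 * ga1.t();      // 27 x c1

  NumericMatrix gw1m(gw1.n_rows, gw1.n_cols), gw2m(gw2.n_rows, gw2.n_cols);
  std::copy(gw1.memptr(), gw1.memptr() + gw1.n_elem, gw1m.begin());
  std::copy(gw2.memptr(), gw2.memptr() + gw2.n_elem, gw2m.begin());
  NumericVector gg1v(c1), gb1vv(c1), gg2v(c2), gb2vv(c2);
  for (int c = 0; c < c1; ++c) { gg1v[c] = gg1[c]; gb1vv[c] = gb1v[c]; }
  for (int c = 0; c < c2; ++c) { gg2v[c] = gg2[c]; gb2vv[c] = gb2v[c]; }
  return List::create(_["gw1"] = gw1m, _["ggamma1"] = gg1v,
                      _["gbeta1"] = gb1vv,
                      _["gw2"] = gw2m, _["ggamma2"] = gg2v,
                      _["gbeta2"] = gb2vv);
}


// ----------------------------------------------- fused 2-d unit pieces --
//
// The ShuffleNetV2 units decompose into 1x1 conv + BN (+ ReLU) and 3x3
// depthwise conv + BN blocks. Each block is fused into one call that
// works in single precision with a persistent scratch cache, like the
// 3-d stem.

struct PwCache {
  arma::fmat xf, z;
  arma::fvec m, is;
};

// variant of bn_bw_f without the ReLU mask
static void bn_bw_f_lin(arma::fmat& ga, const arma::fmat& z,
                        const arma::fvec& mean, const arma::fvec& invstd,
                        const NumericVector& gamma, arma::fvec& ggamma,
                        arma::fvec& gbeta) {
  const int C = ga.n_rows;
  const size_t M = ga.n_cols;
  ggamma.zeros(C);
  gbeta.zeros(C);
  std::vector<float> gam(C);
  for (int c = 0; c < C; ++c) gam[c] = (float)REAL(gamma)[c];
  for (size_t m = 0; m < M; ++m) {
    const float* gv = ga.colptr(m);
    const float* zv = z.colptr(m);
    for (int c = 0; c < C; ++c) {
      const float xhat = (zv[c] - mean[c]) * invstd[c];
      gbeta[c] += gv[c];
      ggamma[c] += gv[c] * xhat;
    }
  }
  const float invM = 1.0f / (float)M;
  for (size_t m = 0; m < M; ++m) {
    float* gv = ga.colptr(m);
    const float* zv = z.colptr(m);
    for (int c = 0; c < C; ++c) {
      const float xhat = (zv[c] - mean[c]) * invstd[c];
      gv[c] = gam[c] * invstd[c] *
        (gv[c] - invM * (float)gbeta[c] - xhat * invM * (float)ggamma[c]);
    }
  }
}

// 1x1 conv + BN + optional ReLU on a channel-first tensor seen as C x M.
// [[Rcpp::export]]
List cpp_pwbr_fw(NumericVector x, int C, NumericMatrix w,
                 NumericVector gamma, NumericVector beta,
                 NumericVector rmean, NumericVector rvar,
                 double eps, bool relu, bool training,
                 SEXP prev = R_NilValue) {
  const size_t M = x.size() / C;
  const int Cout = w.ncol();
  XPtr<PwCache> xp = Rf_isNull(prev)
    ? XPtr<PwCache>(new PwCache(), true) : XPtr<PwCache>(prev);
  PwCache& cc = *xp;
  cc.xf.set_size(C, M);
  std::copy(REAL(x), REAL(x) + x.size(), cc.xf.memptr());
  cc.z = to_fmat(w).t() * cc.xf;  // Cout x M
  arma::fvec sc(Cout), sh(Cout);
  if (training) {
    bn_stats_f(cc.z, cc.m, cc.is, (float)eps);
    for (int c = 0; c < Cout; ++c) {
      sc[c] = (float)REAL(gamma)[c] * cc.is[c];
      sh[c] = (float)REAL(beta)[c] - cc.m[c] * sc[c];
    }
  } else {
    for (int c = 0; c < Cout; ++c) {
      const float is = 1.0f / std::sqrt((float)REAL(rvar)[c] + (float)eps);
      sc[c] = (float)REAL(gamma)[c] * is;
      sh[c] = (float)REAL(beta)[c] - (float)REAL(rmean)[c] * sc[c];
    }
  }
  NumericVector y((size_t)Cout * M);
  double* yp = REAL(y);
  for (size_t m = 0; m < M; ++m) {
    const float* zv = cc.z.colptr(m);
    double* yv = yp + (size_t)Cout * m;
    for (int c = 0; c < Cout; ++c) {
      const float v = sc[c] * zv[c] + sh[c];
      yv[c] = relu ? (v > 0 ? v : 0) : v;
    }
  }
  List out = List::create(_["y"] = y, _["cache"] = xp);
  if (training) {
    NumericVector bm(Cout), bv(Cout);
    for (int c = 0; c < Cout; ++c) {
      bm[c] = cc.m[c];
      bv[c] = 1.0 / ((double)cc.is[c] * cc.is[c]) - eps;
    }
    out["bm"] = bm;
    out["bv"] = bv;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_pwbr_bw(SEXP cacheptr, NumericVector gy, NumericMatrix w,
                 NumericVector gamma, NumericVector beta, bool relu) {
  XPtr<PwCache> cc(cacheptr);
  const int Cout = w.ncol();
  const size_t M = gy.size() / Cout;
  arma::fmat ga(Cout, M);
  std::copy(REAL(gy), REAL(gy) + gy.size(), ga.memptr());
  arma::fvec gg, gb;
  if (relu) bn_bw_f(ga, cc->z, cc->m, cc->is, gamma, beta, gg, gb);
  else bn_bw_f_lin(ga, cc->z, cc->m, cc->is, gamma, gg, gb);
  arma::fmat gw = cc->xf * ga.t();   // C x Cout
  arma::fmat gx = to_fmat(w) * ga;   // C x M
  NumericMatrix gwm(gw.n_rows, gw.n_cols);
  std::copy(gw.memptr(), gw.memptr() + gw.n_elem, gwm.begin());
  NumericVector gxv(gx.n_elem);
  std::copy(gx.memptr(), gx.memptr() + gx.n_elem, REAL(gxv));
  NumericVector ggv(gg.n_elem), gbv(gb.n_elem);
  for (size_t c = 0; c < gg.n_elem; ++c) { ggv[c] = gg[c]; gbv[c] = gb[c]; }
  return List::create(_["gx"] = gxv, _["gw"] = gwm,
                      _["ggamma"] = ggv, _["gbeta"] = gbv);
}

struct DwCache {
  arma::fmat xf, z;
  arma::fvec m, is;
};

static void dwconv2d_f(const float* x, int C, int H, int W, int N,
                       const float* w, int k, int s, int p, float* y) {
  const int OH = out_len(H, k, s, p), OW = out_len(W, k, s, p);
  std::fill(y, y + (size_t)C * OH * OW * N, 0.0f);
  for (int n = 0; n < N; ++n) {
    const float* xn = x + (size_t)n * C * H * W;
    float* yn = y + (size_t)n * C * OH * OW;
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        float* yv = yn + (size_t)C * (oh + (size_t)OH * ow);
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * s - p + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * s - p + kh;
            if (ih < 0 || ih >= H) continue;
            const float* xv = xn + (size_t)C * (ih + (size_t)H * iw);
            const float* wv = w + (size_t)C * (kh + k * kw);
            for (int c = 0; c < C; ++c) yv[c] += wv[c] * xv[c];
          }
        }
      }
  }
}

// 3x3 depthwise conv + BN (no activation, per the unit design).
// [[Rcpp::export]]
List cpp_dwbn_fw(NumericVector x, IntegerVector dims, NumericMatrix w,
                 int k, int s, int p,
                 NumericVector gamma, NumericVector beta,
                 NumericVector rmean, NumericVector rvar,
                 double eps, bool training, SEXP prev = R_NilValue) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int OH = out_len(H, k, s, p), OW = out_len(W, k, s, p);
  const size_t M = (size_t)OH * OW * N;
  XPtr<DwCache> xp = Rf_isNull(prev)
    ? XPtr<DwCache>(new DwCache(), true) : XPtr<DwCache>(prev);
  DwCache& cc = *xp;
  cc.xf.set_size(C, (size_t)H * W * N);
  std::copy(REAL(x), REAL(x) + x.size(), cc.xf.memptr());
  arma::fmat wf = to_fmat(w);
  cc.z.set_size(C, M);
  dwconv2d_f(cc.xf.memptr(), C, H, W, N, wf.memptr(), k, s, p,
             cc.z.memptr());
  arma::fvec sc(C), sh(C);
  if (training) {
    bn_stats_f(cc.z, cc.m, cc.is, (float)eps);
    for (int c = 0; c < C; ++c) {
      sc[c] = (float)REAL(gamma)[c] * cc.is[c];
      sh[c] = (float)REAL(beta)[c] - cc.m[c] * sc[c];
    }
  } else {
    for (int c = 0; c < C; ++c) {
      const float is = 1.0f / std::sqrt((float)REAL(rvar)[c] + (float)eps);
      sc[c] = (float)REAL(gamma)[c] * is;
      sh[c] = (float)REAL(beta)[c] - (float)REAL(rmean)[c] * sc[c];
    }
  }
  NumericVector y((size_t)C * M);
  double* yp = REAL(y);
  for (size_t m = 0; m < M; ++m) {
    const float* zv = cc.z.colptr(m);
    double* yv = yp + (size_t)C * m;
    for (int c = 0; c < C; ++c) yv[c] = sc[c] * zv[c] + sh[c];
  }
  y.attr("dim") = IntegerVector::create(C, OH, OW, N);
  List out = List::create(_["y"] = y, _["cache"] = xp);
  if (training) {
    NumericVector bm(C), bv(C);
    for (int c = 0; c < C; ++c) {
      bm[c] = cc.m[c];
      bv[c] = 1.0 / ((double)cc.is[c] * cc.is[c]) - eps;
    }
    out["bm"] = bm;
    out["bv"] = bv;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dwbn_bw(SEXP cacheptr, IntegerVector dims, NumericVector gy,
                 NumericMatrix w, int k, int s, int p,
                 NumericVector gamma) {
  XPtr<DwCache> cc(cacheptr);
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int OH = out_len(H, k, s, p), OW = out_len(W, k, s, p);
  const size_t M = (size_t)OH * OW * N;
  arma::fmat ga(C, M);
  std::copy(REAL(gy), REAL(gy) + gy.size(), ga.memptr());
  arma::fvec gg, gb;
  bn_bw_f_lin(ga, cc->z, cc->m, cc->is, gamma, gg, gb);
  // depthwise backward
  arma::fmat wf = to_fmat(w);
  arma::fmat gwf(C, k * k, arma::fill::zeros);
  arma::fmat gxf(C, (size_t)H * W * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const float* xn = cc->xf.memptr() + (size_t)n * C * H * W;
    float* gxn = gxf.memptr() + (size_t)n * C * H * W;
    const float* gn = ga.memptr() + (size_t)n * C * OH * OW;
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        const float* gv = gn + (size_t)C * (oh + (size_t)OH * ow);
        for (int kw = 0; kw < k; ++kw) {
          const int iw = ow * s - p + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * s - p + kh;
            if (ih < 0 || ih >= H) continue;
            const size_t off = (size_t)C * (ih + (size_t)H * iw);
            const float* xv = xn + off;
            float* gxv = gxn + off;
            const float* wv = wf.memptr() + (size_t)C * (kh + k * kw);
            float* gwv = gwf.memptr() + (size_t)C * (kh + k * kw);
            for (int c = 0; c < C; ++c) {
              gxv[c] += wv[c] * gv[c];
              gwv[c] += xv[c] * gv[c];
            }
          }
        }
      }
  }
  NumericMatrix gwm(C, k * k);
  std::copy(gwf.memptr(), gwf.memptr() + gwf.n_elem, gwm.begin());
  NumericVector gx(gxf.n_elem);
  std::copy(gxf.memptr(), gxf.memptr() + gxf.n_elem, REAL(gx));
  gx.attr("dim") = dims;
  NumericVector ggv(C), gbv(C);
  for (int c = 0; c < C; ++c) { ggv[c] = gg[c]; gbv[c] = gb[c]; }
  return List::create(_["gx"] = gx, _["gw"] = gwm,
                      _["ggamma"] = ggv, _["gbeta"] = gbv);
}

// ----------------------------------------------------- mask connectivity --

// Connected-component labelling of a binary matrix (BFS). conn = 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int conn) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int>> stack;
  const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int* dr = conn == 8 ? dr8 : dr4;
  const int* dc = conn == 8 ? dc8 : dc4;
  const int nd = conn == 8 ? 8 : 4;
  int next = 0;
  for (int c0 = 0; c0 < W; ++c0)
    for (int r0 = 0; r0 < H; ++r0) {
      if (mask(r0, c0) == 0 || lab(r0, c0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({r0, c0});
      lab(r0, c0) = next;
      while (!stack.empty()) {
        auto rc = stack.back(); stack.pop_back();
        for (int d = 0; d < nd; ++d) {
          const int r = rc.first + dr[d], c = rc.second + dc[d];
          if (r < 0 || r >= H || c < 0 || c >= W) continue;
          if (mask(r, c) != 0 && lab(r, c) == 0) {
            lab(r, c) = next;
            stack.push_back({r, c});
          }
        }
      }
    }
  return lab;
}
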