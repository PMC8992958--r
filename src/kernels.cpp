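// Numerical kernels for the 2D U-Net: convolution forward/backward via
// im2col + GEMM, 2x2 max pooling, nearest-neighbour upsampling, and Keys
// bicubic resampling. Arrays are R column-major with dims (H, W, C, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double at4(const double* x, int H, int W, int C,
                         int h, int w, int c, int n) {
  return x[h + (size_t)H * (w + (size_t)W * (c + (size_t)C * n))];
}

// Fill the im2col patch matrix P ((H*W) x (kh*kw*Cin)) for sample n.
// Zero padding keeps the spatial size; kh, kw odd.
static void im2col(const double* x, int H, int W, int Cin, int n,
                   int kh, int kw, arma::mat& P) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < Cin; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * c);
        for (int w = 0; w < W; ++w) {
          const int iw = w + kj - pw;
          if (iw < 0 || iw >= W) {
            for (int h = 0; h < H; ++h) P(h + H * w, q) = 0.0;
            continue;
          }
          for (int h = 0; h < H; ++h) {
            const int ih = h + ki - ph;
            P(h + H * w, q) =
              (ih < 0 || ih >= H) ? 0.0 : at4(x, H, W, Cin, ih, iw, c, n);
          }
        }
      }
    }
  }
}

// Scatter dP back onto the (padded) input gradient for sample n.
static void col2im(const arma::mat& dP, double* dx, int H, int W, int Cin,
                   int n, int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < Cin; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ki + kh * (kj + kw * c);
        for (int w = 0; w < W; ++w) {
          const int iw = w + kj - pw;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int ih = h + ki - ph;
            if (ih < 0 || ih >= H) continue;
            dx[ih + (size_t)H * (iw + (size_t)W * (c + (size_t)Cin * n))] +=
              dP(h + H * w, q);
          }
        }
      }
    }
  }
}

// x: (H,W,Cin,N); wmat: (kh*kw*Cin) x Cout; bias: Cout. Returns (H,W,Cout,N).
// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, IntegerVector xdim,
                        arma::mat wmat, arma::vec bias, int kh, int kw) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int Cout = wmat.n_cols;
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat P(H * W, kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(REAL(x), H, W, Cin, n, kh, kw, P);
    arma::mat Y = P * wmat;
    Y.each_row() += bias.t();
    std::copy(Y.memptr(), Y.memptr() + Y.n_elem,
              REAL(y) + (size_t)H * W * Cout * n);
  }
  return y;
}

// Gradients of the convolution. Returns list(dx, dw, db); dw has the same
// (kh*kw*Cin) x Cout layout as wmat.
// [[Rcpp::export]]
List conv2d_bw(NumericVector x, IntegerVector xdim, arma::mat wmat,
               NumericVector dy, int kh, int kw) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int Cout = wmat.n_cols;
  NumericVector dx((R_xlen_t)H * W * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat dw(wmat.n_rows, wmat.n_cols, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat P(H * W, kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(REAL(x), H, W, Cin, n, kh, kw, P);
    arma::mat dY(const_cast<double*>(REAL(dy)) + (size_t)H * W * Cout * n,
                 H * W, Cout, false, true);
    dw += P.t() * dY;
    db += arma::sum(dY, 0).t();
    arma::mat dP = dY * wmat.t();
    col2im(dP, REAL(dx), H, W, Cin, n, kh, kw);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns the pooled array and the within-block
// argmax (0..3, column-major within the block) needed for the backward pass.
// [[Rcpp::export]]
List maxpool_fw(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* px = REAL(x);
  double* py = REAL(y);
  int* pi = INTEGER(idx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double best = -HUGE_VAL; int barg = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              double v = at4(px, H, W, C, 2 * h + di, 2 * w + dj, c, n);
              if (v > best) { best = v; barg = di + 2 * dj; }
            }
          size_t o = h + (size_t)Ho * (w + (size_t)Wo * (c + (size_t)C * n));
          py[o] = best; pi[o] = barg;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bw(NumericVector dy, IntegerVector idx,
                         IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* pdy = REAL(dy);
  const int* pi = INTEGER(idx);
  double* pdx = REAL(dx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t o = h + (size_t)Ho * (w + (size_t)Wo * (c + (size_t)C * n));
          const int di = pi[o] % 2, dj = pi[o] / 2;
          pdx[(2 * h + di) +
              (size_t)H * ((2 * w + dj) + (size_t)W * (c + (size_t)C * n))] +=
            pdy[o];
        }
  return dx;
}

// Nearest-neighbour x2 upsampling.
// [[Rcpp::export]]
NumericVector upsample_fw(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* px = REAL(x);
  double* py = REAL(y);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          py[h + (size_t)Ho * (w + (size_t)Wo * (c + (size_t)C * n))] =
            at4(px, H, W, C, h / 2, w / 2, c, n);
  return y;
}

// [[Rcpp::export]]
NumericVector upsample_bw(NumericVector dy, IntegerVector ydim) {
  const int Ho = ydim[0], Wo = ydim[1], C = ydim[2], N = ydim[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* pdy = REAL(dy);
  double* pdx = REAL(dx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          pdx[(h / 2) +
              (size_t)H * ((w / 2) + (size_t)W * (c + (size_t)C * n))] +=
            pdy[h + (size_t)Ho * (w + (size_t)Wo * (c + (size_t)C * n))];
  return dx;
}

// Keys cubic-convolution kernel, a = -0.5 (reproduces constants exactly and
// interpolates the samples at integer offsets).
static inline double keys(double t) {
  const double a = -0.5;
  t = std::fabs(t);
  if (t <= 1.0) return (a + 2.0) * t * t * t - (a + 3.0) * t * t + 1.0;
  if (t < 2.0)  return a * t * t * t - 5.0 * a * t * t + 8.0 * a * t - 4.0 * a;
  return 0.0;
}

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

// Separable bicubic resampling of a 2D matrix with edge replication.
// Centre-aligned coordinate mapping: src = (i + 0.5) * (in/out) - 0.5.
// [[Rcpp::export]]
arma::mat resize_bicubic(arma::mat img, int out_h, int out_w) {
  const int H = img.n_rows, W = img.n_cols;
  const double sh = (double)H / out_h, sw = (double)W / out_w;
  // rows first
  arma::mat tmp(out_h, W);
  for (int i = 0; i < out_h; ++i) {
    const double s = (i + 0.5) * sh - 0.5;
    const int i0 = (int)std::floor(s);
    double wk[4];
    for (int k = 0; k < 4; ++k) wk[k] = keys(s - (i0 - 1 + k));
    for (int j = 0; j < W; ++j) {
      double acc = 0.0;
      for (int k = 0; k < 4; ++k)
        acc += wk[k] * img(clampi(i0 - 1 + k, 0, H - 1), j);
      tmp(i, j) = acc;
    }
  }
  arma::mat out(out_h, out_w);
  for (int j = 0; j < out_w; ++j) {
    const double s = (j + 0.5) * sw - 0.5;
    const int j0 = (int)std::floor(s);
    double wk[4];
    for (int k = 0; k < 4; ++k) wk[k] = keys(s - (j0 - 1 + k));
    for (int i = 0; i < out_h; ++i) {
      double acc = 0.0;
      for (int k = 0; k < 4; ++k)
        acc += wk[k] * tmp(i, clampi(j0 - 1 + k, 0, W - 1));
      out(i, j) = acc;
    }
  }
  return out;
}
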