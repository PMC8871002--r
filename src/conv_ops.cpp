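// Convolutional primitives for the encoder-decoder FCN.
//
// Tensor layout follows R's column-major arrays:
//   activations  (H, W, C, N)
//   conv weights (kh, kw, Cin, Cout)
//   transpose-conv weights (kh, kw, Cout, Cin)  -- channels-out third, as
//     printed in the architecture table (4 x 4 x 16 x 64).
//
// Convolutions are same-padded (odd kernels); implemented as im2col + GEMM.
// The transpose convolution uses stride 2 and kernel 4; its raw output of
// size 2H+2 is symmetrically cropped by one pixel per side to exactly 2H.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void im2col_same(const double* xs, int H, int W, int Ci,
                               int kh, int kw, arma::mat& M) {
  // M is (H*W) x (kh*kw*Ci); column q = ki + kh*(kj + kw*ci)
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  M.zeros();
  for (int ci = 0; ci < Ci; ++ci) {
    const double* xc = xs + (size_t)H * W * ci;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* Mcol = M.colptr(ki + kh * (kj + kw * ci));
        for (int wj = 0; wj < W; ++wj) {
          const int sj = wj + kj - pw;
          if (sj < 0 || sj >= W) continue;
          const int lo = std::max(0, ph - ki);
          const int hi = std::min(H, H + ph - ki);
          const double* src = xc + (size_t)H * sj;
          double* dst = Mcol + (size_t)H * wj;
          for (int i = lo; i < hi; ++i) dst[i] = src[i + ki - ph];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  if (wd[2] != Ci) stop("conv2d_fw: weight Cin %d != input channels %d", (int)wd[2], Ci);
  arma::mat Wm(w.begin(), (size_t)kh * kw * Ci, Co, false);
  NumericVector y((size_t)H * W * Co * N);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  arma::mat M(H * W, kh * kw * Ci);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (size_t)H * W * Ci * n, H, W, Ci, kh, kw, M);
    arma::mat Y(y.begin() + (size_t)H * W * Co * n, H * W, Co, false, true);
    Y = M * Wm;
    for (int co = 0; co < Co; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::mat Wm(w.begin(), (size_t)kh * kw * Ci, Co, false);
  NumericVector dx((size_t)H * W * Ci * N), dwv((size_t)kh * kw * Ci * Co);
  dx.attr("dim") = xd;
  dwv.attr("dim") = wd;
  NumericVector db(Co);
  arma::mat dW(dwv.begin(), (size_t)kh * kw * Ci, Co, false, true);
  arma::mat M(H * W, kh * kw * Ci);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (size_t)H * W * Ci * n, H, W, Ci, kh, kw, M);
    arma::mat dY((double*)dy.begin() + (size_t)H * W * Co * n, H * W, Co, false);
    dW += M.t() * dY;
    for (int co = 0; co < Co; ++co) db[co] += arma::accu(dY.col(co));
    arma::mat dM = dY * Wm.t();          // (H*W) x (kh*kw*Ci)
    double* dxs = dx.begin() + (size_t)H * W * Ci * n;
    for (int ci = 0; ci < Ci; ++ci) {
      double* dxc = dxs + (size_t)H * W * ci;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const double* Mcol = dM.colptr(ki + kh * (kj + kw * ci));
          for (int wj = 0; wj < W; ++wj) {
            const int sj = wj + kj - pw;
            if (sj < 0 || sj >= W) continue;
            const int lo = std::max(0, ph - ki);
            const int hi = std::min(H, H + ph - ki);
            double* dst = dxc + (size_t)H * sj;
            const double* src = Mcol + (size_t)H * wj;
            for (int i = lo; i < hi; ++i) dst[i + ki - ph] += src[i];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool_fw: spatial dims must be even, got %d x %d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // 0-based linear index into x
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wj = 0; wj < Wo; ++wj)
        for (int hi = 0; hi < Ho; ++hi, ++o) {
          size_t p00 = base + (2 * hi) + (size_t)H * (2 * wj);
          size_t best = p00;
          double v = x[p00];
          const size_t cand[3] = {p00 + 1, p00 + (size_t)H, p00 + (size_t)H + 1};
          for (int k = 0; k < 3; ++k)
            if (x[cand[k]] > v) { v = x[cand[k]]; best = cand[k]; }
          y[o] = v;
          idx[o] = (int)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(IntegerVector idx, NumericVector dy, IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dx[idx[i]] += dy[i];
  return dx;
}

// [[Rcpp::export(name = ".tconv_fw")]]
NumericVector tconv_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[2];
  if (wd[3] != Ci) stop("tconv_fw: weight Cin %d != input channels %d", (int)wd[3], Ci);
  const int Hf = 2 * H + 2, Wf = 2 * W + 2;   // raw stride-2 output, kernel 4
  NumericVector y((size_t)(2 * H) * (2 * W) * Co * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, Co, N);
  arma::mat Wk(Ci, Co);
  arma::cube yfull(Hf, Wf, Co);
  for (int n = 0; n < N; ++n) {
    arma::mat Xn((double*)x.begin() + (size_t)H * W * Ci * n, H * W, Ci, false);
    yfull.zeros();
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        for (int ci = 0; ci < Ci; ++ci)
          for (int co = 0; co < Co; ++co)
            Wk(ci, co) = w[ki + kh * (kj + (size_t)kw * (co + (size_t)Co * ci))];
        arma::mat Cm = Xn * Wk;            // (H*W) x Co
        for (int co = 0; co < Co; ++co) {
          const double* src = Cm.colptr(co);
          for (int j = 0; j < W; ++j) {
            double* dst = yfull.slice_colptr(co, 2 * j + kj);
            const double* s = src + (size_t)H * j;
            for (int i = 0; i < H; ++i) dst[2 * i + ki] += s[i];
          }
        }
      }
    // symmetric crop: rows/cols 1 .. 2H (0-based), add bias
    double* yo = y.begin() + (size_t)(2 * H) * (2 * W) * Co * n;
    for (int co = 0; co < Co; ++co)
      for (int j = 0; j < 2 * W; ++j) {
        const double* src = yfull.slice_colptr(co, j + 1) + 1;
        double* dst = yo + (size_t)(2 * H) * (j + (size_t)(2 * W) * co);
        for (int i = 0; i < 2 * H; ++i) dst[i] = src[i] + b[co];
      }
  }
  return y;
}

// [[Rcpp::export(name = ".tconv_bw")]]
List tconv_bw(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[2];
  const int Hf = 2 * H + 2, Wf = 2 * W + 2;
  NumericVector dx((size_t)H * W * Ci * N), dwv(w.size());
  dx.attr("dim") = xd;
  dwv.attr("dim") = wd;
  NumericVector db(Co);
  arma::mat Wk(Ci, Co), dWk(Ci, Co);
  arma::cube dyfull(Hf, Wf, Co);
  arma::mat G(H * W, Co);
  for (int n = 0; n < N; ++n) {
    arma::mat Xn((double*)x.begin() + (size_t)H * W * Ci * n, H * W, Ci, false);
    arma::mat dXn(dx.begin() + (size_t)H * W * Ci * n, H * W, Ci, false, true);
    // un-crop: place dy into the interior of the raw-output grid
    dyfull.zeros();
    const double* dyo = dy.begin() + (size_t)(2 * H) * (2 * W) * Co * n;
    for (int co = 0; co < Co; ++co)
      for (int j = 0; j < 2 * W; ++j) {
        const double* src = dyo + (size_t)(2 * H) * (j + (size_t)(2 * W) * co);
        double* dst = dyfull.slice_colptr(co, j + 1) + 1;
        for (int i = 0; i < 2 * H; ++i) { dst[i] = src[i]; db[co] += src[i]; }
      }
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        for (int ci = 0; ci < Ci; ++ci)
          for (int co = 0; co < Co; ++co)
            Wk(ci, co) = w[ki + kh * (kj + (size_t)kw * (co + (size_t)Co * ci))];
        for (int co = 0; co < Co; ++co) {
          double* g = G.colptr(co);
          for (int j = 0; j < W; ++j) {
            const double* src = dyfull.slice_colptr(co, 2 * j + kj);
            double* dst = g + (size_t)H * j;
            for (int i = 0; i < H; ++i) dst[i] = src[2 * i + ki];
          }
        }
        dXn += G * Wk.t();
        dWk = Xn.t() * G;
        for (int ci = 0; ci < Ci; ++ci)
          for (int co = 0; co < Co; ++co)
            dwv[ki + kh * (kj + (size_t)kw * (co + (size_t)Co * ci))] += dWk(ci, co);
      }
  }
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}
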