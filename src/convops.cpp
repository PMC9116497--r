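// Batched 2-D convolution primitives for the U-Net, stride 1, zero padding.
// Arrays use R's column-major layout with dimensions (H, W, C, N) for data
// and (kh, kw, Cin, Cout) for kernels. Convolution is implemented as
// im2col followed by a BLAS matrix product, which is where almost all of
// the training time is spent.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int pt, int pl,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int q = i + kh * (j + kw * c);
        double* dst = col.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo - pl + j;
          double* d = dst + (size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            std::fill(d, d + Ho, 0.0);
            continue;
          }
          const double* xcol = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho - pt + i;
            d[ho] = (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& dcol, int H, int W, int C,
                       int kh, int kw, int pt, int pl,
                       int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int q = i + kh * (j + kw * c);
        const double* src = dcol.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo - pl + j;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)H * wi;
          const double* s = src + (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho - pt + i;
            if (hi >= 0 && hi < H) xcol[hi] += s[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int pt, int pb, int pl, int pr) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("channel mismatch");
  int Ho = H + pt + pb - kh + 1, Wo = W + pl + pr - kw + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  arma::mat W2(w.begin(), (size_t)kh * kw * C, Cout, false, true);
  arma::rowvec bv(b.begin(), Cout);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col((size_t)Ho * Wo, (size_t)kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, pt, pl,
           Ho, Wo, col);
    arma::mat Y(y.begin() + (size_t)Ho * Wo * Cout * n,
                (size_t)Ho * Wo, Cout, false, true);
    Y = col * W2;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int pt, int pb, int pl, int pr) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = H + pt + pb - kh + 1, Wo = W + pl + pr - kw + 1;
  arma::mat W2(w.begin(), (size_t)kh * kw * C, Cout, false, true);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dW2(dw.begin(), (size_t)kh * kw * C, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat col((size_t)Ho * Wo, (size_t)kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, pt, pl,
           Ho, Wo, col);
    arma::mat dY((double*)dy.begin() + (size_t)Ho * Wo * Cout * n,
                 (size_t)Ho * Wo, Cout, false, true);
    dW2 += col.t() * dY;
    dbv += arma::sum(dY, 0);
    arma::mat dcol = dY * W2.t();
    col2im_add(dcol, H, W, C, kh, kw, pt, pl, Ho, Wo,
               dx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
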