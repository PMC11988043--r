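// im2col-based 2-D convolution kernels used by the autodiff layer.
// Array layout follows R column-major order throughout:
//   activations x : dim (H, W, C, N)
//   weights     w : dim (kh, kw, Cin/groups, Cout)
// so x[h + H*(w + W*(c + C*n))] and column-major im2col matrices feed
// straight into BLAS GEMM via Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Fill M (kh*kw*Cg x Ho*Wo) for one sample/group. Row index r = i + kh*(j + kw*ci),
// column index = ho + Ho*wo; zero padding outside the frame.
static void im2col(const double* x, int H, int W, int c0, int Cg,
                   int kh, int kw, int stride, int pad, int dil,
                   int Ho, int Wo, arma::mat& M) {
  for (int ci = 0; ci < Cg; ++ci) {
    const double* xc = x + (size_t)(c0 + ci) * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int iw = wo * stride - pad + j * dil;
          double* Mcol = M.memptr() + (size_t)r + (size_t)M.n_rows * (size_t)(Ho * wo);
          if (iw < 0 || iw >= W) {
            for (int ho = 0; ho < Ho; ++ho) Mcol[(size_t)M.n_rows * ho] = 0.0;
            continue;
          }
          for (int ho = 0; ho < Ho; ++ho) {
            int ih = ho * stride - pad + i * dil;
            Mcol[(size_t)M.n_rows * ho] =
              (ih < 0 || ih >= H) ? 0.0 : xc[ih + (size_t)H * iw];
          }
        }
      }
    }
  }
}

// scatter-add of columns back to the input plane (adjoint of im2col)
static void col2im_acc(const arma::mat& M, double* gx, int H, int W, int c0, int Cg,
                       int kh, int kw, int stride, int pad, int dil,
                       int Ho, int Wo) {
  for (int ci = 0; ci < Cg; ++ci) {
    double* gc = gx + (size_t)(c0 + ci) * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int iw = wo * stride - pad + j * dil;
          if (iw < 0 || iw >= W) continue;
          const double* Mcol = M.memptr() + (size_t)r + (size_t)M.n_rows * (size_t)(Ho * wo);
          for (int ho = 0; ho < Ho; ++ho) {
            int ih = ho * stride - pad + i * dil;
            if (ih < 0 || ih >= H) continue;
            gc[ih + (size_t)H * iw] += Mcol[(size_t)M.n_rows * ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, Nullable<NumericVector> bias,
                         int stride, int pad, int dil, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  if (C != Cg * groups) stop("conv2d: channel/group mismatch");
  int Ho = out_size(H, kh, stride, pad, dil), Wo = out_size(W, kw, stride, pad, dil);
  int Cog = Cout / groups;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat M(kh * kw * Cg, Ho * Wo);
  const double* b = bias.isNotNull() ? NumericVector(bias).begin() : nullptr;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    double* yn = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, g * Cg, Cg, kh, kw, stride, pad, dil, Ho, Wo, M);
      arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)g * Cog * kh * kw * Cg,
                   kh * kw * Cg, Cog, false, true);
      arma::mat Yg(yn + (size_t)g * Cog * Ho * Wo, Ho * Wo, Cog, false, true);
      Yg = M.t() * Wg;
      if (b)
        for (int co = 0; co < Cog; ++co) Yg.col(co) += b[g * Cog + co];
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad, int dil, int groups,
                bool need_gx, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  int Cog = Cout / groups;

  NumericVector gw((size_t)kh * kw * Cg * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(has_bias ? Cout : 0);
  NumericVector gx(need_gx ? x.size() : 0);
  if (need_gx) gx.attr("dim") = xd;

  arma::mat M(kh * kw * Cg, Ho * Wo);
  arma::mat Gm(kh * kw * Cg, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    const double* gyn = gy.begin() + (size_t)n * Ho * Wo * Cout;
    for (int g = 0; g < groups; ++g) {
      arma::mat Gy(const_cast<double*>(gyn) + (size_t)g * Cog * Ho * Wo,
                   Ho * Wo, Cog, false, true);
      im2col(xn, H, W, g * Cg, Cg, kh, kw, stride, pad, dil, Ho, Wo, M);
      arma::mat GW(gw.begin() + (size_t)g * Cog * kh * kw * Cg,
                   kh * kw * Cg, Cog, false, true);
      GW += M * Gy;
      if (has_bias)
        for (int co = 0; co < Cog; ++co) gb[g * Cog + co] += arma::accu(Gy.col(co));
      if (need_gx) {
        arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)g * Cog * kh * kw * Cg,
                     kh * kw * Cg, Cog, false, true);
        Gm = Wg * Gy.t();
        col2im_acc(Gm, gx.begin() + (size_t)n * H * W * C, H, W, g * Cg, Cg,
                   kh, kw, stride, pad, dil, Ho, Wo);
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
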