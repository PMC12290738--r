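#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored column-major as H x W x C x N arrays.  im2col
// unrolls k x k patches so that a 2D convolution becomes a single GEMM with
// the (k*k*C) x Cout weight matrix; col2im scatters gradients back.  Rows of
// the patch matrix are ordered (ho, wo, n) with ho fastest; columns are
// ordered (kh, kw, c) with kh fastest.

// [[Rcpp::export]]
NumericMatrix im2col_hwcn(NumericVector x, int H, int W, int C, int N,
                          int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(Ho * (R_xlen_t)Wo * N, k * k * C);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t nrow = (R_xlen_t)Ho * Wo * N;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double* ocol = op + ((R_xlen_t)kh + k * ((R_xlen_t)kw + k * c)) * nrow;
        for (int n = 0; n < N; ++n) {
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + kw - pad;
            double* orow = ocol + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
            if (wi < 0 || wi >= W) {
              for (int ho = 0; ho < Ho; ++ho) orow[ho] = 0.0;
              continue;
            }
            const double* xcol =
                xp + (R_xlen_t)H * (wi + (R_xlen_t)W * (c + (R_xlen_t)C * n));
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + kh - pad;
              orow[ho] = (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_hwcn(NumericMatrix cols, int H, int W, int C, int N,
                          int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)H * W * C * N);
  double* xp = x.begin();
  const double* cp = cols.begin();
  const R_xlen_t nrow = (R_xlen_t)Ho * Wo * N;
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double* ccol =
            cp + ((R_xlen_t)kh + k * ((R_xlen_t)kw + k * c)) * nrow;
        for (int n = 0; n < N; ++n) {
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + kw - pad;
            if (wi < 0 || wi >= W) continue;
            const double* crow = ccol + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
            double* xcol =
                xp + (R_xlen_t)H * (wi + (R_xlen_t)W * (c + (R_xlen_t)C * n));
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + kh - pad;
              if (hi >= 0 && hi < H) xcol[hi] += crow[ho];
            }
          }
        }
      }
    }
  }
  return x;
}
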