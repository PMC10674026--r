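#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays in [H, W, C, N] layout (column-major).  im2col lowers a
// batched convolution to one GEMM: rows index (ki, kj, c) exactly as R flattens
// a weight array of dim c(k, k, C, Cout); columns index (ho, wo, n).

static inline int out_size(int in, int k, int pad, int stride, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int k, int pad, int stride, int dil) {
  const int Ho = out_size(H, k, pad, stride, dil);
  const int Wo = out_size(W, k, pad, stride, dil);
  NumericMatrix cols(k * k * C, Ho * Wo * N);
  const double *px = x.begin();
  double *pc = cols.begin();
  const int nrow = k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        double *dst = pc + col * nrow;
        for (int c = 0; c < C; ++c) {
          const double *src = px + (R_xlen_t)H * (W * ((R_xlen_t)c + (R_xlen_t)C * n));
          for (int kj = 0; kj < k; ++kj) {
            const int w_in = wo * stride - pad + kj * dil;
            for (int ki = 0; ki < k; ++ki) {
              const int h_in = ho * stride - pad + ki * dil;
              double v = 0.0;
              if (h_in >= 0 && h_in < H && w_in >= 0 && w_in < W)
                v = src[h_in + (R_xlen_t)H * w_in];
              dst[ki + k * (kj + k * c)] = v;
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int pad, int stride, int dil) {
  const int Ho = out_size(H, k, pad, stride, dil);
  const int Wo = out_size(W, k, pad, stride, dil);
  NumericVector x((R_xlen_t)H * W * C * N);
  double *px = x.begin();
  const double *pc = cols.begin();
  const int nrow = k * k * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        const double *src = pc + col * nrow;
        for (int c = 0; c < C; ++c) {
          double *dst = px + (R_xlen_t)H * (W * ((R_xlen_t)c + (R_xlen_t)C * n));
          for (int kj = 0; kj < k; ++kj) {
            const int w_in = wo * stride - pad + kj * dil;
            if (w_in < 0 || w_in >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int h_in = ho * stride - pad + ki * dil;
              if (h_in < 0 || h_in >= H) continue;
              dst[h_in + (R_xlen_t)H * w_in] += src[ki + k * (kj + k * c)];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}
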