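#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// Same-padding stride-1 convolution as a sum of per-tap GEMMs.  The array
// layout [H, W, C, N] makes each sample a column-major (H*W) x C matrix with
// contiguous columns, so each kernel tap contributes one dgemm against a
// zero-bordered shifted copy of the sample.  This keeps intermediates at the
// size of one activation instead of the k^2-fold im2col blow-up.

static void shift_copy(const double *x, double *s, int H, int W, int C,
                       int di, int dj) {
  // s[h, w, c] = x[h + di, w + dj, c], zero outside
  const int HW = H * W;
  std::fill(s, s + (size_t)HW * C, 0.0);
  const int h0 = std::max(0, -di), h1 = std::min(H, H - di);
  const int w0 = std::max(0, -dj), w1 = std::min(W, W - dj);
  if (h0 >= h1 || w0 >= w1) return;
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)HW * c;
    double *sc = s + (size_t)HW * c;
    for (int w = w0; w < w1; ++w) {
      std::copy(xc + (size_t)H * (w + dj) + h0 + di,
                xc + (size_t)H * (w + dj) + h1 + di,
                sc + (size_t)H * w + h0);
    }
  }
}

static void shift_add(const double *t, double *dx, int H, int W, int C,
                      int di, int dj) {
  // dx[h + di, w + dj, c] += t[h, w, c], clipped to the border
  const int HW = H * W;
  const int h0 = std::max(0, -di), h1 = std::min(H, H - di);
  const int w0 = std::max(0, -dj), w1 = std::min(W, W - dj);
  if (h0 >= h1 || w0 >= w1) return;
  for (int c = 0; c < C; ++c) {
    const double *tc = t + (size_t)HW * c;
    double *dc = dx + (size_t)HW * c;
    for (int w = w0; w < w1; ++w) {
      const double *src = tc + (size_t)H * w + h0;
      double *dst = dc + (size_t)H * (w + dj) + h0 + di;
      for (int h = h0; h < h1; ++h) *dst++ += *src++;
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int H, int W, int C, int N, int k, int dil) {
  const int Cout = b.size();
  const int HW = H * W;
  const int half = (k - 1) / 2;
  NumericVector y((size_t)HW * Cout * N);
  std::vector<double> s((size_t)HW * C);
  std::vector<double> wk((size_t)C * Cout);
  const double one = 1.0;
  for (int n = 0; n < N; ++n) {
    double *yn = y.begin() + (size_t)HW * Cout * n;
    for (int co = 0; co < Cout; ++co)
      std::fill(yn + (size_t)HW * co, yn + (size_t)HW * (co + 1), b[co]);
    const double *xn = x.begin() + (size_t)HW * C * n;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int di = (ki - half) * dil, dj = (kj - half) * dil;
        // tap weights: w[ki, kj, c, co] -> wk (C x Cout)
        for (int co = 0; co < Cout; ++co)
          for (int c = 0; c < C; ++c)
            wk[c + (size_t)C * co] =
              w[ki + k * (kj + k * ((size_t)c + (size_t)C * co))];
        const double *xs;
        if (di == 0 && dj == 0) xs = xn;
        else { shift_copy(xn, s.data(), H, W, C, di, dj); xs = s.data(); }
        F77_CALL(dgemm)("N", "N", &HW, &Cout, &C, &one, xs, &HW,
                        wk.data(), &C, &one, yn, &HW FCONE FCONE);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int H, int W, int C, int N, int k, int dil) {
  const int Cout = w.size() / (k * k * C);
  const int HW = H * W;
  const int half = (k - 1) / 2;
  NumericVector dx((size_t)HW * C * N);
  NumericVector dw(w.size());
  NumericVector db(Cout);
  std::vector<double> s((size_t)HW * C);
  std::vector<double> t((size_t)HW * C);
  std::vector<double> wk((size_t)C * Cout);
  std::vector<double> dwk((size_t)C * Cout);
  const double one = 1.0, zero = 0.0;
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + (size_t)HW * C * n;
    const double *dyn = dy.begin() + (size_t)HW * Cout * n;
    double *dxn = dx.begin() + (size_t)HW * C * n;
    for (int co = 0; co < Cout; ++co) {
      const double *d = dyn + (size_t)HW * co;
      double acc = 0.0;
      for (int i = 0; i < HW; ++i) acc += d[i];
      db[co] += acc;
    }
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int di = (ki - half) * dil, dj = (kj - half) * dil;
        for (int co = 0; co < Cout; ++co)
          for (int c = 0; c < C; ++c)
            wk[c + (size_t)C * co] =
              w[ki + k * (kj + k * ((size_t)c + (size_t)C * co))];
        const double *xs;
        if (di == 0 && dj == 0) xs = xn;
        else { shift_copy(xn, s.data(), H, W, C, di, dj); xs = s.data(); }
        // dWk = S^T (C x HW) . dY (HW x Cout)
        F77_CALL(dgemm)("T", "N", &C, &Cout, &HW, &one, xs, &HW,
                        dyn, &HW, &zero, dwk.data(), &C FCONE FCONE);
        for (int co = 0; co < Cout; ++co)
          for (int c = 0; c < C; ++c)
            dw[ki + k * (kj + k * ((size_t)c + (size_t)C * co))] +=
              dwk[c + (size_t)C * co];
        // T = dY (HW x Cout) . Wk^T (Cout x C); dx[h+di, w+dj] += T[h, w]
        F77_CALL(dgemm)("N", "T", &HW, &C, &Cout, &one, dyn, &HW,
                        wk.data(), &C, &zero, t.data(), &HW FCONE FCONE);
        if (di == 0 && dj == 0) {
          double *d = dxn;
          const double *src = t.data();
          for (size_t i = 0; i < (size_t)HW * C; ++i) d[i] += src[i];
        } else {
          shift_add(t.data(), dxn, H, W, C, di, dj);
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  IntegerVector wd = IntegerVector::create(k, k, C, Cout);
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
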