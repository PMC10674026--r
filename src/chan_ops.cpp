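#include <Rcpp.h>
using namespace Rcpp;

// Per-channel helpers on [H, W, C, N] arrays: index i has channel
// c = (i / HW) % C.  Used by batch normalisation and channel concatenation,
// where R-level rep()/aperm() expansions dominate otherwise.

// [[Rcpp::export]]
NumericVector chan_sum_cpp(NumericVector x, int HW, int C, int N) {
  NumericVector out(C);
  const double *p = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double acc = 0.0;
      for (int i = 0; i < HW; ++i) acc += *p++;
      out[c] += acc;
    }
  return out;
}

// [[Rcpp::export]]
NumericVector chan_dot_cpp(NumericVector x, NumericVector y, int HW, int C,
                           int N) {
  NumericVector out(C);
  const double *px = x.begin(), *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double acc = 0.0;
      for (int i = 0; i < HW; ++i) acc += (*px++) * (*py++);
      out[c] += acc;
    }
  return out;
}

// y = a[c] * x + b[c]
// [[Rcpp::export]]
NumericVector chan_affine_cpp(NumericVector x, NumericVector a,
                              NumericVector b, int HW, int C, int N) {
  NumericVector y(x.size());
  const double *px = x.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c];
      for (int i = 0; i < HW; ++i) *py++ = ac * (*px++) + bc;
    }
  y.attr("dim") = x.attr("dim");
  return y;
}

// y = a[c] * u + b[c] * v + d[c]   (batch-norm backward combination)
// [[Rcpp::export]]
NumericVector chan_affine2_cpp(NumericVector u, NumericVector v,
                               NumericVector a, NumericVector b,
                               NumericVector d, int HW, int C, int N) {
  NumericVector y(u.size());
  const double *pu = u.begin(), *pv = v.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c], dc = d[c];
      for (int i = 0; i < HW; ++i) *py++ = ac * (*pu++) + bc * (*pv++) + dc;
    }
  y.attr("dim") = u.attr("dim");
  return y;
}

// Channel-wise concatenation of arrays sharing (H, W, N).
// [[Rcpp::export]]
NumericVector concat_chan_cpp(List xs, int HW, IntegerVector cs, int N) {
  const int K = xs.size();
  int Ctot = 0;
  for (int k = 0; k < K; ++k) Ctot += cs[k];
  NumericVector y((size_t)HW * Ctot * N);
  double *py = y.begin();
  std::vector<const double *> ps(K);
  for (int k = 0; k < K; ++k) ps[k] = as<NumericVector>(xs[k]).begin();
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < K; ++k) {
      const size_t len = (size_t)HW * cs[k];
      const double *src = ps[k] + (size_t)HW * cs[k] * n;
      std::copy(src, src + len, py);
      py += len;
    }
  return y;
}

// Inverse of concat_chan_cpp: slice channels [c0, c0+cc) out of x.
// [[Rcpp::export]]
NumericVector slice_chan_cpp(NumericVector x, int HW, int C, int N, int c0,
                             int cc) {
  NumericVector y((size_t)HW * cc * N);
  double *py = y.begin();
  for (int n = 0; n < N; ++n) {
    const double *src = x.begin() + (size_t)HW * (C * n + c0);
    std::copy(src, src + (size_t)HW * cc, py);
    py += (size_t)HW * cc;
  }
  return y;
}

// Fused per-channel mean and mean-of-squares (batch-norm statistics).
// [[Rcpp::export]]
List chan_meanvar_cpp(NumericVector x, int HW, int C, int N) {
  NumericVector mu(C), ex2(C);
  const double *p = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int i = 0; i < HW; ++i) { const double v = *p++; s += v; s2 += v * v; }
      mu[c] += s; ex2[c] += s2;
    }
  const double M = (double)HW * N;
  for (int c = 0; c < C; ++c) { mu[c] /= M; ex2[c] /= M; }
  return List::create(_["mu"] = mu, _["ex2"] = ex2);
}

// y[h,w,c,n] = a[h,w,c,n] * b[h,w,1,n]  (channel broadcast of b)
// [[Rcpp::export]]
NumericVector bcast_mul_cpp(NumericVector a, NumericVector b, int HW, int C,
                            int N) {
  NumericVector y(a.size());
  const double *pa = a.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n) {
    const double *pb = b.begin() + (size_t)HW * n;
    for (int c = 0; c < C; ++c)
      for (int i = 0; i < HW; ++i) *py++ = (*pa++) * pb[i];
  }
  y.attr("dim") = a.attr("dim");
  return y;
}

// out[h,w,1,n] = sum_c a[h,w,c,n] * b[h,w,c,n]
// [[Rcpp::export]]
NumericVector bcast_dot_cpp(NumericVector a, NumericVector b, int HW, int C,
                            int N) {
  NumericVector y((size_t)HW * N);
  const double *pa = a.begin(), *pb = b.begin();
  for (int n = 0; n < N; ++n) {
    double *py = y.begin() + (size_t)HW * n;
    for (int c = 0; c < C; ++c)
      for (int i = 0; i < HW; ++i) py[i] += (*pa++) * (*pb++);
  }
  return y;
}

// Pin OpenBLAS to one thread when present: the GEMMs here are small and
// thread spin-up/contention dominates on few-core machines.  Weak symbol so
// other BLAS implementations are untouched.
extern "C" void openblas_set_num_threads(int) __attribute__((weak));

// [[Rcpp::export]]
void blas_single_thread_cpp() {
  if (openblas_set_num_threads) openblas_set_num_threads(1);
}
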