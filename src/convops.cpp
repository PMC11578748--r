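#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Feature tensors are R arrays with dim (C, H, W, N): channel index fastest.
// im2col rows are ordered (c fastest, then kernel-row kh, then kernel-col kw)
// so a weight matrix of dim (Cout, C*k*k) with the same column order turns
// convolution into one GEMM: Y = Wmat %*% col.

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int C, int H, int W, int N,
                         int k, int s, int p) {
  const int Ho = out_size(H, k, s, p);
  const int Wo = out_size(W, k, s, p);
  const int rows = C * k * k;
  const int cols = Ho * Wo * N;
  NumericMatrix col(rows, cols);
  const double* xp = x.begin();
  double* cp = col.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int q = ho + Ho * (wo + Wo * n);
        double* colq = cp + (size_t)q * rows;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * s - p + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * s - p + kh;
            double* dst = colq + C * (kh + k * kw);
            if (hi < 0 || hi >= H || wi < 0 || wi >= W) {
              for (int c = 0; c < C; ++c) dst[c] = 0.0;
            } else {
              const double* src = xp + (size_t)C * (hi + H * ((size_t)wi + (size_t)W * n));
              for (int c = 0; c < C; ++c) dst[c] = src[c];
            }
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix col, int C, int H, int W, int N,
                         int k, int s, int p) {
  const int Ho = out_size(H, k, s, p);
  const int Wo = out_size(W, k, s, p);
  NumericVector x((size_t)C * H * W * N);
  double* xp = x.begin();
  const double* cp = col.begin();
  const int rows = C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int q = ho + Ho * (wo + Wo * n);
        const double* colq = cp + (size_t)q * rows;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * s - p + kw;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * s - p + kh;
            if (hi < 0 || hi >= H) continue;
            const double* src = colq + C * (kh + k * kw);
            double* dst = xp + (size_t)C * (hi + H * ((size_t)wi + (size_t)W * n));
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int C, int H, int W, int N,
                     int k, int s, int p) {
  const int Ho = out_size(H, k, s, p);
  const int Wo = out_size(W, k, s, p);
  NumericVector y((size_t)C * Ho * Wo * N);
  IntegerVector arg((size_t)C * Ho * Wo * N); // 0-based index into x
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        for (int c = 0; c < C; ++c) {
          double best = -DBL_MAX;
          size_t besti = 0;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wo * s - p + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = ho * s - p + kh;
              if (hi < 0 || hi >= H) continue;
              const size_t idx = c + (size_t)C * (hi + H * ((size_t)wi + (size_t)W * n));
              if (xp[idx] > best) { best = xp[idx]; besti = idx; }
            }
          }
          const size_t oidx = c + (size_t)C * (ho + Ho * ((size_t)wo + (size_t)Wo * n));
          yp[oidx] = best;
          ap[oidx] = (int)besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector arg, int size) {
  NumericVector dx(size);
  double* dp = dx.begin();
  const double* gp = dy.begin();
  const int* ap = arg.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dp[ap[i]] += gp[i];
  return dx;
}
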