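// Compiled inner loops of the preprocessing pipeline: zero-phase IIR
// filtering of pixel columns, per-pixel clipping, separable spatial
// Gaussian blur of frame stacks, and spatial medians.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// direct-form II transposed single pass, in place
static void df2t(std::vector<double>& x, const std::vector<double>& b,
                 const std::vector<double>& a) {
  const int k = (int)b.size();
  std::vector<double> z(k, 0.0);
  for (size_t n = 0; n < x.size(); ++n) {
    const double xn = x[n];
    const double yn = b[0] * xn + z[0];
    for (int i = 1; i < k; ++i)
      z[i - 1] = b[i] * xn + z[i] - a[i] * yn;
    x[n] = yn;
  }
}

// Forward-backward filter of each column, replicating signal::filtfilt
// padding semantics: append 2*k zeros, filter, reverse, filter, reverse,
// keep the first n samples.
// [[Rcpp::export]]
NumericMatrix filtfilt_cols_cpp(NumericMatrix x, NumericVector b_,
                                NumericVector a_) {
  const int n = x.nrow(), p = x.ncol();
  const int k = std::max(b_.size(), a_.size());
  std::vector<double> b(k, 0.0), a(k, 0.0);
  for (int i = 0; i < b_.size(); ++i) b[i] = b_[i] / a_[0];
  for (int i = 0; i < a_.size(); ++i) a[i] = a_[i] / a_[0];
  const int npad = 2 * k;
  NumericMatrix out(n, p);
  std::vector<double> col((size_t)n + npad);
  for (int j = 0; j < p; ++j) {
    std::fill(col.begin(), col.end(), 0.0);
    for (int i = 0; i < n; ++i) col[i] = x(i, j);
    df2t(col, b, a);
    std::reverse(col.begin(), col.end());
    df2t(col, b, a);
    std::reverse(col.begin(), col.end());
    for (int i = 0; i < n; ++i) out(i, j) = col[i];
  }
  return out;
}

// clamp each column j of x into [lo[j], hi[j]], in a fresh matrix
// [[Rcpp::export]]
NumericMatrix clip_cols_cpp(NumericMatrix x, NumericVector lo,
                            NumericVector hi) {
  const int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    const double l = lo[j], h = hi[j];
    for (int i = 0; i < n; ++i) {
      double v = x(i, j);
      out(i, j) = v < l ? l : (v > h ? h : v);
    }
  }
  return out;
}

// whole-sample reflection, folded until inside [0, n); supports kernels
// wider than the image
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n - 2;
  i = ((i % period) + period) % period;
  if (i >= n) i = period - i;
  return i;
}

// separable Gaussian blur (reflect padding) of every frame of a T x H x W
// stack, kernel centered (odd length)
// [[Rcpp::export]]
NumericVector gauss_blur_frames_cpp(NumericVector stack, IntegerVector dims,
                                    NumericVector kernel) {
  const int T = dims[0], H = dims[1], W = dims[2];
  const int r = ((int)kernel.size() - 1) / 2;
  NumericVector tmp(stack.size()), out(stack.size());
  const double* in = stack.begin();
  // blur along rows (H)
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      double* o = tmp.begin() + (size_t)T * (h + (size_t)H * w);
      for (int j = -r; j <= r; ++j) {
        const double k = kernel[j + r];
        const double* s = in + (size_t)T * (reflect_idx(h + j, H) + (size_t)H * w);
        for (int t = 0; t < T; ++t) o[t] += k * s[t];
      }
    }
  }
  // blur along columns (W)
  const double* in2 = tmp.begin();
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      double* o = out.begin() + (size_t)T * (h + (size_t)H * w);
      for (int j = -r; j <= r; ++j) {
        const double k = kernel[j + r];
        const double* s = in2 + (size_t)T * (h + (size_t)H * reflect_idx(w + j, W));
        for (int t = 0; t < T; ++t) o[t] += k * s[t];
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// median of each row of a matrix
// [[Rcpp::export]]
NumericVector row_medians_cpp(NumericMatrix x) {
  const int n = x.nrow(), p = x.ncol();
  NumericVector out(n);
  std::vector<double> buf(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) buf[j] = x(i, j);
    const int mid = p / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double m = buf[mid];
    if (p % 2 == 0) {
      std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
      m = 0.5 * (m + buf[mid - 1]);
    }
    out[i] = m;
  }
  return out;
}
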