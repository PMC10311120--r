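// im2col gather and its transpose scatter for 3x3 convolutions.
// These are the only hot loops of the native U-Net; everything else is
// BLAS matrix products. `taps` holds, per kernel offset, the 1-based
// linear indices into the zero-padded activation stack.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_gather(const NumericMatrix& P, const IntegerMatrix& taps) {
  const int n = taps.nrow();      // output pixels (nb * H * W)
  const int C = P.ncol();
  NumericMatrix col(n, 9 * C);
  const double* p = P.begin();
  const int nP = P.nrow();
  double* out = col.begin();
  for (int k = 0; k < 9; ++k) {
    const int* idx = &taps(0, k);
    for (int c = 0; c < C; ++c) {
      const double* src = p + (size_t)c * nP;
      double* dst = out + ((size_t)(k * C + c)) * n;
      for (int i = 0; i < n; ++i) dst[i] = src[idx[i] - 1];
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericMatrix col2im_scatter(const NumericMatrix& dcol, const IntegerMatrix& taps,
                             const int n_padded, const IntegerVector& interior) {
  const int n = taps.nrow();
  const int C = dcol.ncol() / 9;
  NumericMatrix dP(n_padded, C);
  const double* dc = dcol.begin();
  double* out = dP.begin();
  for (int k = 0; k < 9; ++k) {
    const int* idx = &taps(0, k);
    for (int c = 0; c < C; ++c) {
      const double* src = dc + ((size_t)(k * C + c)) * n;
      double* dst = out + (size_t)c * n_padded;
      for (int i = 0; i < n; ++i) dst[idx[i] - 1] += src[i];
    }
  }
  // return only the interior (unpadded) rows
  const int ni = interior.size();
  NumericMatrix dX(ni, C);
  for (int c = 0; c < C; ++c) {
    const double* src = out + (size_t)c * n_padded;
    double* dst = dX.begin() + (size_t)c * ni;
    for (int i = 0; i < ni; ++i) dst[i] = src[interior[i] - 1];
  }
  return dX;
}
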