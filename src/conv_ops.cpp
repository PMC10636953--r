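#include <Rcpp.h>
using namespace Rcpp;

// Gather the 3x3 neighbourhood of every pixel into im2col layout.
// X: n x cin feature matrix (pixel-major), idx: n x 9 one-based neighbour
// indices with 0 marking out-of-bounds (zero padding).
// Returns n x (9 * cin).
// [[Rcpp::export(name = ".cpp_im2col")]]
NumericMatrix cpp_im2col(const NumericMatrix& X, const IntegerMatrix& idx) {
  const int n = X.nrow(), cin = X.ncol();
  NumericMatrix out(n, 9 * cin);
  for (int k = 0; k < 9; ++k) {
    const int* id = &idx(0, k);
    for (int c = 0; c < cin; ++c) {
      const double* src = &X(0, c);
      double* dst = &out(0, k * cin + c);
      for (int i = 0; i < n; ++i) {
        const int j = id[i];
        dst[i] = j > 0 ? src[j - 1] : 0.0;
      }
    }
  }
  return out;
}

// Scatter-accumulate the im2col-layout gradient back onto the input grid
// (transpose of cpp_im2col). dYW: n x (9 * cin), idx as above.
// Returns n x cin.
// [[Rcpp::export(name = ".cpp_col2im")]]
NumericMatrix cpp_col2im(const NumericMatrix& dYW, const IntegerMatrix& idx,
                         const int cin) {
  const int n = dYW.nrow();
  NumericMatrix out(n, cin);
  for (int k = 0; k < 9; ++k) {
    const int* id = &idx(0, k);
    for (int c = 0; c < cin; ++c) {
      const double* src = &dYW(0, k * cin + c);
      double* dst = &out(0, c);
      for (int i = 0; i < n; ++i) {
        const int j = id[i];
        if (j > 0) dst[j - 1] += src[i];
      }
    }
  }
  return out;
}
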