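#include <Rcpp.h>
using namespace Rcpp;

// Patch-matrix extraction for 3x3 same-padding convolution.
// x is an (H, W, C) column-major array; the result has one row per pixel
// and 9*C columns, ordered tap-major (dx outer, dy inner) with channels
// fastest within a tap, matching the weight layout used by the R engine.

// [[Rcpp::export]]
NumericMatrix cpp_im2col3(NumericVector x, int H, int W, int C) {
  NumericMatrix out(H * W, 9 * C);
  for (int k = 0; k < 9; ++k) {
    int dx = k / 3, dy = k % 3;
    for (int c = 0; c < C; ++c) {
      double* col = &out(0, k * C + c);
      const double* plane = &x[c * H * W];
      for (int j = 0; j < W; ++j) {
        int sj = j + dx - 1;
        double* dst = col + j * H;
        if (sj < 0 || sj >= W) {
          for (int i = 0; i < H; ++i) dst[i] = 0.0;
          continue;
        }
        const double* src = plane + sj * H;
        for (int i = 0; i < H; ++i) {
          int si = i + dy - 1;
          dst[i] = (si >= 0 && si < H) ? src[si] : 0.0;
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col3: scatter-add a patch-matrix gradient back into
// an (H, W, C) input-gradient array.

// [[Rcpp::export]]
NumericVector cpp_col2im3(NumericMatrix Xg, int H, int W, int C) {
  NumericVector out(H * W * C);
  for (int k = 0; k < 9; ++k) {
    int dx = k / 3, dy = k % 3;
    for (int c = 0; c < C; ++c) {
      const double* col = &Xg(0, k * C + c);
      double* plane = &out[c * H * W];
      for (int j = 0; j < W; ++j) {
        int sj = j + dx - 1;
        if (sj < 0 || sj >= W) continue;
        const double* src = col + j * H;
        double* dst = plane + sj * H;
        for (int i = 0; i < H; ++i) {
          int si = i + dy - 1;
          if (si >= 0 && si < H) dst[si] += src[i];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}
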