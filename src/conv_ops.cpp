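// 3x3 same-padding convolution support: im2col gather and its adjoint
// scatter-add. Activations are (H*W) x channels matrices in column-major
// pixel order; patch columns are ordered channel-major, then column offset,
// then row offset. The matrix products themselves stay in R (BLAS).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col3(const NumericMatrix& A, int H, int W) {
  const int C = A.ncol();
  const int HW = H * W;
  NumericMatrix out(HW, 9 * C);
  for (int ch = 0; ch < C; ++ch) {
    const double* a = &A(0, ch);
    int k = ch * 9;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        double* o = &out(0, k++);
        for (int c = 0; c < W; ++c) {
          const int sc = c + dc;
          if (sc < 0 || sc >= W) continue;  // zero padding
          const double* acol = a + sc * H;
          double* ocol = o + c * H;
          const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          for (int r = r0; r < r1; ++r) ocol[r] = acol[r + dr];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix col2im3(const NumericMatrix& dP, int H, int W) {
  const int C = dP.ncol() / 9;
  NumericMatrix dA(H * W, C);
  for (int ch = 0; ch < C; ++ch) {
    double* a = &dA(0, ch);
    int k = ch * 9;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const double* o = &dP(0, k++);
        for (int c = 0; c < W; ++c) {
          const int sc = c + dc;
          if (sc < 0 || sc >= W) continue;
          double* acol = a + sc * H;
          const double* ocol = o + c * H;
          const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          for (int r = r0; r < r1; ++r) acol[r + dr] += ocol[r];
        }
      }
    }
  }
  return dA;
}
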