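// Hot loops of the convolution machinery: neighbourhood unfolding
// (im2col) and its adjoint scatter-add (col2im), plus the layout
// permutations between the (H, W, N, C)-flattened GEMM result and the
// package's (H, W, C, N) tensor convention. Layouts mirror the
// reference R implementations exactly (see R/nn.R), which the test
// suite asserts.

#include <Rcpp.h>
using namespace Rcpp;

// Unfold k x k neighbourhoods (zero 'same' padding) of an H x W x C x N
// tensor into an (H*W*N) x (k*k*C) matrix. Row order: (pixel-within-
// image column-major, image); column blocks: offset-major (dx outer,
// dy inner), channel within block.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int k) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int p = (k - 1) / 2;
  const R_xlen_t nrow = (R_xlen_t)H * W * N;
  NumericMatrix out(nrow, (R_xlen_t)k * k * C);
  const double* xp = x.begin();
  double* op = out.begin();
  int blk = 0;
  for (int dx = 0; dx < k; ++dx) {
    for (int dy = 0; dy < k; ++dy, ++blk) {
      for (int c = 0; c < C; ++c) {
        double* col = op + ((R_xlen_t)blk * C + c) * nrow;
        for (int n = 0; n < N; ++n) {
          const double* src = xp + ((R_xlen_t)n * C + c) * H * W;
          double* dst = col + (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dx - p;
            double* dcol = dst + (R_xlen_t)w * H;
            if (sw < 0 || sw >= W) {
              for (int h = 0; h < H; ++h) dcol[h] = 0.0;
              continue;
            }
            const double* scol = src + (R_xlen_t)sw * H;
            for (int h = 0; h < H; ++h) {
              const int sh = h + dy - p;
              dcol[h] = (sh < 0 || sh >= H) ? 0.0 : scol[sh];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add column gradients back into an
// H x W x C x N tensor.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int k, int H, int W, int C,
                         int N) {
  const int p = (k - 1) / 2;
  const R_xlen_t nrow = (R_xlen_t)H * W * N;
  NumericVector out((R_xlen_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  double* op = out.begin();
  const double* cp = cols.begin();
  int blk = 0;
  for (int dx = 0; dx < k; ++dx) {
    for (int dy = 0; dy < k; ++dy, ++blk) {
      for (int c = 0; c < C; ++c) {
        const double* col = cp + ((R_xlen_t)blk * C + c) * nrow;
        for (int n = 0; n < N; ++n) {
          double* dst = op + ((R_xlen_t)n * C + c) * H * W;
          const double* src = col + (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dx - p;
            if (sw < 0 || sw >= W) continue;
            double* dcol = dst + (R_xlen_t)sw * H;
            const double* scol = src + (R_xlen_t)w * H;
            for (int h = 0; h < H; ++h) {
              const int sh = h + dy - p;
              if (sh >= 0 && sh < H) dcol[sh] += scol[h];
            }
          }
        }
      }
    }
  }
  return out;
}

// (H*W*N) x C GEMM result -> H x W x C x N tensor.
// [[Rcpp::export]]
NumericVector hwnc_to_tensor(NumericMatrix y, int H, int W, int N) {
  const int C = y.ncol();
  NumericVector out((R_xlen_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  double* op = out.begin();
  const double* yp = y.begin();
  const R_xlen_t hw = (R_xlen_t)H * W;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const double* src = yp + c * hw * N + n * hw;
      double* dst = op + ((R_xlen_t)n * C + c) * hw;
      std::copy(src, src + hw, dst);
    }
  return out;
}

// H x W x C x N tensor -> (H*W*N) x C matrix (inverse of the above).
// [[Rcpp::export]]
NumericMatrix tensor_to_hwnc(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const R_xlen_t hw = (R_xlen_t)H * W;
  NumericMatrix out(hw * N, C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const double* src = xp + ((R_xlen_t)n * C + c) * hw;
      double* dst = op + c * hw * N + n * hw;
      std::copy(src, src + hw, dst);
    }
  return out;
}
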