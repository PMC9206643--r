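// Direct 'same'-padding convolution as a sum of per-offset GEMMs
// against R's BLAS, avoiding the materialization of the full unfolded
// neighbourhood matrix. Semantics are identical to the im2col route
// (R/nn.R reference implementations); the test suite asserts the
// equivalence.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Copy the (dy, dx) shifted slab of x (H x W x C x N, zero padding)
// into buf as an (H*W*N) x C column-major matrix.
static void shift_block(const double* xp, double* buf, int H, int W, int C,
                        int N, int dy, int dx, int p) {
  const R_xlen_t nrow = (R_xlen_t)H * W * N;
  for (int c = 0; c < C; ++c) {
    double* col = buf + (R_xlen_t)c * nrow;
    for (int n = 0; n < N; ++n) {
      const double* src = xp + ((R_xlen_t)n * C + c) * H * W;
      double* dst = col + (R_xlen_t)n * H * W;
      for (int w = 0; w < W; ++w) {
        const int sw = w + dx - p;
        double* dcol = dst + (R_xlen_t)w * H;
        if (sw < 0 || sw >= W) {
          std::fill(dcol, dcol + H, 0.0);
          continue;
        }
        const double* scol = src + (R_xlen_t)sw * H;
        const int h0 = std::max(0, p - dy);
        const int h1 = std::min(H, H + p - dy);
        if (h0 > 0) std::fill(dcol, dcol + h0, 0.0);
        for (int h = h0; h < h1; ++h) dcol[h] = scol[h + dy - p];
        if (h1 < H) std::fill(dcol + h1, dcol + H, 0.0);
      }
    }
  }
}

// Scatter-add buf ((H*W*N) x C, the gradient flowing through the
// (dy, dx) offset) back into dx_out at the shifted source positions.
static void shift_block_add(double* dxp, const double* buf, int H, int W,
                            int C, int N, int dy, int dx, int p) {
  const R_xlen_t nrow = (R_xlen_t)H * W * N;
  for (int c = 0; c < C; ++c) {
    const double* col = buf + (R_xlen_t)c * nrow;
    for (int n = 0; n < N; ++n) {
      double* dst = dxp + ((R_xlen_t)n * C + c) * H * W;
      const double* src = col + (R_xlen_t)n * H * W;
      for (int w = 0; w < W; ++w) {
        const int sw = w + dx - p;
        if (sw < 0 || sw >= W) continue;
        double* dcol = dst + (R_xlen_t)sw * H;
        const double* scol = src + (R_xlen_t)w * H;
        const int h0 = std::max(0, p - dy);
        const int h1 = std::min(H, H + p - dy);
        for (int h = h0; h < h1; ++h) dcol[h + dy - p] += scol[h];
      }
    }
  }
}

// Forward convolution: returns H x W x Cout x N tensor.
// W is (k*k*Cin) x Cout with offset-major row blocks (dx outer, dy
// inner), matching the im2col layout.
// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, NumericMatrix Wm,
                           NumericVector b, int k) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], Wd = d[1], C = d[2], N = d[3];
  const int Cout = Wm.ncol();
  const int p = (k - 1) / 2;
  const R_xlen_t nrow = (R_xlen_t)H * Wd * N;
  std::vector<double> buf(nrow * C);
  std::vector<double> y(nrow * Cout);
  for (int c = 0; c < Cout; ++c)
    std::fill(y.begin() + c * nrow, y.begin() + (c + 1) * nrow, b[c]);
  const int m = (int)nrow, nn = Cout, kk = C, ldw = Wm.nrow();
  const double one = 1.0;
  int blk = 0;
  for (int dx = 0; dx < k; ++dx)
    for (int dy = 0; dy < k; ++dy, ++blk) {
      shift_block(x.begin(), buf.data(), H, Wd, C, N, dy, dx, p);
      // y += buf (m x kk) * W[blk*C .. , ] (kk x nn)
      F77_CALL(dgemm)("N", "N", &m, &nn, &kk, &one, buf.data(), &m,
                      &Wm(blk * C, 0), &ldw, &one, y.data(), &m
                      FCONE FCONE);
    }
  // (H*W*N) x Cout -> H x W x Cout x N
  NumericVector out((R_xlen_t)H * Wd * Cout * N);
  out.attr("dim") = IntegerVector::create(H, Wd, Cout, N);
  const R_xlen_t hw = (R_xlen_t)H * Wd;
  for (int c = 0; c < Cout; ++c)
    for (int n = 0; n < N; ++n)
      std::copy(y.begin() + c * nrow + n * hw, y.begin() + c * nrow + (n + 1) * hw,
                out.begin() + ((R_xlen_t)n * Cout + c) * hw);
  return out;
}

// Backward convolution: given input x, weights and the output gradient
// dy (H x W x Cout x N), returns dx, dW, db.
// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector x, NumericMatrix Wm, NumericVector dy,
                  int k) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], Wd = d[1], C = d[2], N = d[3];
  const int Cout = Wm.ncol();
  const int p = (k - 1) / 2;
  const R_xlen_t nrow = (R_xlen_t)H * Wd * N;
  const R_xlen_t hw = (R_xlen_t)H * Wd;
  // dy tensor -> (H*W*N) x Cout
  std::vector<double> dym(nrow * Cout);
  for (int c = 0; c < Cout; ++c)
    for (int n = 0; n < N; ++n)
      std::copy(dy.begin() + ((R_xlen_t)n * Cout + c) * hw,
                dy.begin() + ((R_xlen_t)n * Cout + c + 1) * hw,
                dym.begin() + c * nrow + n * hw);
  NumericVector db(Cout);
  for (int c = 0; c < Cout; ++c) {
    double s = 0.0;
    const double* col = dym.data() + c * nrow;
    for (R_xlen_t i = 0; i < nrow; ++i) s += col[i];
    db[c] = s;
  }
  NumericMatrix dW(Wm.nrow(), Cout);
  NumericVector dxv((R_xlen_t)H * Wd * C * N);
  dxv.attr("dim") = IntegerVector::create(H, Wd, C, N);
  std::vector<double> buf(nrow * C);
  const int m = (int)nrow, nn = Cout, kk = C, ldw = Wm.nrow();
  const double one = 1.0, zero = 0.0;
  int blk = 0;
  for (int dx = 0; dx < k; ++dx)
    for (int dy_ = 0; dy_ < k; ++dy_, ++blk) {
      shift_block(x.begin(), buf.data(), H, Wd, C, N, dy_, dx, p);
      // dW_blk (kk x nn) = buf^T (kk x m) * dym (m x nn)
      F77_CALL(dgemm)("T", "N", &kk, &nn, &m, &one, buf.data(), &m,
                      dym.data(), &m, &zero, &dW(blk * C, 0), &ldw
                      FCONE FCONE);
      // dcols (m x kk) = dym (m x nn) * W_blk^T (nn x kk)
      F77_CALL(dgemm)("N", "T", &m, &kk, &nn, &one, dym.data(), &m,
                      &Wm(blk * C, 0), &ldw, &zero, buf.data(), &m
                      FCONE FCONE);
      shift_block_add(REAL(dxv), buf.data(), H, Wd, C, N, dy_, dx, p);
    }
  return List::create(_["dx"] = dxv, _["dW"] = dW, _["db"] = db);
}
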