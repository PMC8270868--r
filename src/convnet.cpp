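// Dilated 3x3 convolution primitives (same padding) for the residual
// restoration network, via im2col + GEMM. Weight layout: w is a
// (Cin*9) x Cout matrix whose row index is c*9 + 3*kj + ki, with ki/kj the
// kernel row/column offset indices (0..2) and spatial offsets
// ((ki-1)*dil, (kj-1)*dil). Cubes are H x W x C, matching R arrays
// dim = c(H, W, C).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col3(const cube& x, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat M(H * W, C * 9, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int kj = 0; kj < 3; ++kj) {
      const int oj = (kj - 1) * dil;
      for (int ki = 0; ki < 3; ++ki) {
        const int oi = (ki - 1) * dil;
        const int col = c * 9 + 3 * kj + ki;
        for (int j = 0; j < W; ++j) {
          const int js = j + oj;
          if (js < 0 || js >= W) continue;
          const int ilo = std::max(0, -oi), ihi = std::min(H, H - oi);
          double* dst = M.colptr(col) + (size_t)j * H;
          const double* src = xs.colptr(js);
          for (int i = ilo; i < ihi; ++i) dst[i] = src[i + oi];
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int dil) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat M = im2col3(x, dil);
  mat Y = M * w;
  Y.each_row() += b.t();
  cube out(H, W, Cout);
  std::memcpy(out.memptr(), Y.memptr(), sizeof(double) * Y.n_elem);
  return out;
}

// Gradients of the same convolution. gy is H x W x Cout; returns gx (like x),
// gw (like w) and gb (like b). gx is computed by scattering gy through the
// transposed kernel (col2im of gy * w^T).
// [[Rcpp::export]]
Rcpp::List cpp_conv2d_backward(const arma::cube& x, const arma::mat& w,
                               const arma::cube& gy, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = gy.n_slices;
  mat M = im2col3(x, dil);
  mat GY((double*)gy.memptr(), (size_t)H * W, Cout, false, true);
  mat gw = M.t() * GY;
  vec gb = sum(GY, 0).t();
  mat GXcol = GY * w.t(); // (H*W) x (C*9)
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& gs = gx.slice(c);
    for (int kj = 0; kj < 3; ++kj) {
      const int oj = (kj - 1) * dil;
      for (int ki = 0; ki < 3; ++ki) {
        const int oi = (ki - 1) * dil;
        const int col = c * 9 + 3 * kj + ki;
        for (int j = 0; j < W; ++j) {
          const int js = j + oj;
          if (js < 0 || js >= W) continue;
          const int ilo = std::max(0, -oi), ihi = std::min(H, H - oi);
          double* dst = gs.colptr(js);
          const double* src = GXcol.colptr(col) + (size_t)j * H;
          for (int i = ilo; i < ihi; ++i) dst[i + oi] += src[i];
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}
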