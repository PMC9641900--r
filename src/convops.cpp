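// Minimal convolution primitives for the landmark heatmap network.
// Tensors cross the R boundary as arma::cube with dimensions (H, W, C).
// Convolutions are im2col-based so the inner product runs through BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// column matrix of kernel patches: rows = C*kh*kw, cols = Ho*Wo
static mat im2col(const cube& x, int kh, int kw, int stride, int pad,
                  int Ho, int Wo) {
  const int C = x.n_slices;
  mat cols(C * kh * kw, Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& plane = x.slice(c);
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const int row = c * kh * kw + ki * kw + kj;
        for (int oi = 0; oi < Ho; ++oi) {
          const int ii = oi * stride + ki - pad;
          if (ii < 0 || ii >= (int)x.n_rows) continue;
          for (int oj = 0; oj < Wo; ++oj) {
            const int jj = oj * stride + kj - pad;
            if (jj < 0 || jj >= (int)x.n_cols) continue;
            cols(row, oi * Wo + oj) = plane(ii, jj);
          }
        }
      }
    }
  }
  return cols;
}

static void col2im(const mat& cols, cube& gx, int kh, int kw, int stride,
                   int pad, int Ho, int Wo) {
  const int C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    mat& plane = gx.slice(c);
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const int row = c * kh * kw + ki * kw + kj;
        for (int oi = 0; oi < Ho; ++oi) {
          const int ii = oi * stride + ki - pad;
          if (ii < 0 || ii >= (int)gx.n_rows) continue;
          for (int oj = 0; oj < Wo; ++oj) {
            const int jj = oj * stride + kj - pad;
            if (jj < 0 || jj >= (int)gx.n_cols) continue;
            plane(ii, jj) += cols(row, oi * Wo + oj);
          }
        }
      }
    }
  }
}

// forward convolution: x (H,W,C), w (K rows, C*kh*kw cols), b length K
// [[Rcpp::export]]
arma::cube conv2dForward(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b, int kh, int kw, int stride,
                         int pad) {
  const int Ho = (x.n_rows + 2 * pad - kh) / stride + 1;
  const int Wo = (x.n_cols + 2 * pad - kw) / stride + 1;
  mat cols = im2col(x, kh, kw, stride, pad, Ho, Wo);
  mat y = w * cols;             // K x (Ho*Wo)
  y.each_col() += b;
  cube out(Ho, Wo, w.n_rows);
  for (uword k = 0; k < w.n_rows; ++k)
    out.slice(k) = reshape(y.row(k).t(), Wo, Ho).t();
  return out;
}

// backward: returns list(gx, gw, gb)
// [[Rcpp::export]]
Rcpp::List conv2dBackward(const arma::cube& x, const arma::mat& w,
                          const arma::cube& gy, int kh, int kw, int stride,
                          int pad) {
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  const int K = gy.n_slices;
  mat gyMat(K, Ho * Wo);
  for (int k = 0; k < K; ++k)
    gyMat.row(k) = vectorise(gy.slice(k).t()).t();
  mat cols = im2col(x, kh, kw, stride, pad, Ho, Wo);
  mat gw = gyMat * cols.t();
  vec gb = sum(gyMat, 1);
  mat gcols = w.t() * gyMat;
  cube gx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  col2im(gcols, gx, kh, kw, stride, pad, Ho, Wo);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}
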