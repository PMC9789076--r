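// Minimal 2D convolution kernels (im2col) backing the small encoder-decoder
// segmenter. All convolutions are 'same' (zero-padded), stride 1, square
// kernels of odd size. Layouts: images are H x W x C cubes; a weight matrix
// has (k*k*Cin) rows and Cout columns, with row index varying fastest over
// (di, dj, cin) in that order.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = k / 2;
  arma::mat cols(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * (dj + k * c);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - p;
            if (si < 0 || si >= H) continue;
            cols(i + H * j, col) = x(si, sj, c);
          }
        }
      }
    }
  }
  return cols;
}

static arma::cube col2im(const arma::mat& dcols, int H, int W, int C, int k) {
  const int p = k / 2;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * (dj + k * c);
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - p;
            if (si < 0 || si >= H) continue;
            dx(si, sj, c) += dcols(i + H * j, col);
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube conv2d_forward(const arma::cube& x, const arma::mat& w,
                          const arma::vec& bias, int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat y = im2col(x, k) * w;
  y.each_row() += bias.t();
  arma::cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(y.col(c), H, W);
  return out;
}

// [[Rcpp::export]]
List conv2d_backward(const arma::cube& x, const arma::mat& w,
                     const arma::cube& dy, int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  arma::mat dyMat(H * W, Cout);
  for (int c = 0; c < Cout; ++c)
    dyMat.col(c) = arma::vectorise(dy.slice(c));
  arma::mat cols = im2col(x, k);
  arma::mat dw = cols.t() * dyMat;
  arma::vec db = arma::sum(dyMat, 0).t();
  arma::cube dx = col2im(dyMat * w.t(), H, W, Cin, k);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; odd trailing row/col is pooled over the
// available 1- or 2-element window. Returns pooled cube and the linear
// (1-based, per input cube) index of each selected maximum for backprop.
// [[Rcpp::export]]
List maxpool2_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int dj = 0; dj < 2; ++dj) {
          const int j = 2 * jo + dj; if (j >= W) continue;
          for (int di = 0; di < 2; ++di) {
            const int i = 2 * io + di; if (i >= H) continue;
            const double v = x(i, j, c);
            if (v > best) { best = v; bi = i + H * (j + W * (arma::uword)c); }
          }
        }
        y(io, jo, c) = best;
        idx(io, jo, c) = bi + 1;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_backward(const arma::ucube& idx, const arma::cube& dy,
                             int H, int W) {
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (arma::uword n = 0; n < idx.n_elem; ++n)
    dx(idx(n) - 1) += dy(n);
  return dx;
}
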