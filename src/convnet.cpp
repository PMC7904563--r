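// Minimal CNN primitives for the junction segmentation network:
// same-padded k x k convolution via im2col + BLAS gemm, 2x2 average
// pooling and nearest-neighbour upsampling, each with its adjoint.
// Activations are cubes (H, W, C); weights are (C_out, C_in*k*k).
// im2col uses a pixel-major (H*W, C*k*k) layout so each feature column is
// filled by contiguous column-segment copies of the source image.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// cols(p, j): patch value of feature j = (ci, kc, kr) at pixel p = r + c*H
static void im2col_pm(const cube &x, int k, mat &cols) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices, pad = k / 2;
  cols.zeros(H * W, C * k * k);
  for (int ci = 0; ci < C; ++ci) {
    const mat &xs = x.slice(ci);
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        int j = ci * k * k + kr * k + kc;
        double *dst = cols.colptr(j);
        for (int c = 0; c < W; ++c) {
          int sc = c + kc - pad;
          if (sc < 0 || sc >= W) continue;
          int r0 = std::max(0, pad - kr), r1 = std::min(H, H + pad - kr);
          if (r1 <= r0) continue;
          const double *src = xs.colptr(sc) + (r0 + kr - pad);
          std::copy(src, src + (r1 - r0), dst + c * H + r0);
        }
      }
    }
  }
}

// adjoint of im2col_pm: scatter-add columns of dcols back into an image
static void col2im_pm(const mat &dcols, int H, int W, int C, int k,
                      cube &dx) {
  int pad = k / 2;
  dx.zeros(H, W, C);
  for (int ci = 0; ci < C; ++ci) {
    mat &dxs = dx.slice(ci);
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        int j = ci * k * k + kr * k + kc;
        const double *src = dcols.colptr(j);
        for (int c = 0; c < W; ++c) {
          int sc = c + kc - pad;
          if (sc < 0 || sc >= W) continue;
          int r0 = std::max(0, pad - kr), r1 = std::min(H, H + pad - kr);
          if (r1 <= r0) continue;
          double *dst = dxs.colptr(sc) + (r0 + kr - pad);
          const double *s = src + c * H + r0;
          for (int t = 0; t < r1 - r0; ++t) dst[t] += s[t];
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube &x, const arma::mat &w,
                        const arma::vec &b, int k) {
  int H = x.n_rows, W = x.n_cols, Cout = w.n_rows;
  mat cols;
  im2col_pm(x, k, cols);
  mat y = cols * w.t();          // (H*W, C_out)
  y.each_row() += b.t();
  cube out(y.memptr(), H, W, Cout);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(const arma::cube &x, const arma::mat &w,
                        const arma::cube &dy, int k) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int Cout = dy.n_slices;
  mat dymat(const_cast<double *>(dy.memptr()), H * W, Cout, false, true);
  mat cols;
  im2col_pm(x, k, cols);
  mat dw = dymat.t() * cols;     // (C_out, C*k*k)
  vec db = sum(dymat, 0).t();
  mat dcols = dymat * w;         // (H*W, C*k*k)
  cube dx;
  col2im_pm(dcols, H, W, C, k, dx);
  return Rcpp::List::create(Rcpp::_["dx"] = dx, Rcpp::_["dw"] = dw,
                            Rcpp::_["db"] = db);
}

// [[Rcpp::export]]
arma::cube cpp_avgpool2(const arma::cube &x) {
  int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube y(H, W, C);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        y(r, c, ci) = 0.25 * (x(2 * r, 2 * c, ci) + x(2 * r + 1, 2 * c, ci) +
                              x(2 * r, 2 * c + 1, ci) +
                              x(2 * r + 1, 2 * c + 1, ci));
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool2_bwd(const arma::cube &dy) {
  int H = dy.n_rows, W = dy.n_cols, C = dy.n_slices;
  cube dx(2 * H, 2 * W, C);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        double g = 0.25 * dy(r, c, ci);
        dx(2 * r, 2 * c, ci) = g;
        dx(2 * r + 1, 2 * c, ci) = g;
        dx(2 * r, 2 * c + 1, ci) = g;
        dx(2 * r + 1, 2 * c + 1, ci) = g;
      }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2(const arma::cube &x) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        double v = x(r, c, ci);
        y(2 * r, 2 * c, ci) = v;
        y(2 * r + 1, 2 * c, ci) = v;
        y(2 * r, 2 * c + 1, ci) = v;
        y(2 * r + 1, 2 * c + 1, ci) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube &dy) {
  int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  cube dx(H, W, C);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        dx(r, c, ci) = dy(2 * r, 2 * c, ci) + dy(2 * r + 1, 2 * c, ci) +
                       dy(2 * r, 2 * c + 1, ci) + dy(2 * r + 1, 2 * c + 1, ci);
  return dx;
}
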