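// Minimal convolution kernels for the silhouette classifier backbone.
// Feature maps are (H, W, C) cubes (R arrays dim c(H, W, C)); weights are
// pre-flattened in R with patch order (di, dj, c) fastest-first, matching
// dim(w) <- c(kh*kw*cin, cout) of an array dim c(kh, kw, cin, cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// standard (grouped = 1) convolution via im2col + GEMM
// [[Rcpp::export]]
arma::cube conv2d_fwd_cpp(const arma::cube& x, const arma::mat& w,
                          int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int K = w.n_cols;
  if ((int)w.n_rows != kh * kw * C)
    Rcpp::stop("conv2d: weight rows do not match kh*kw*C");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::mat A(kh * kw * C, Ho * Wo, arma::fill::zeros);
  for (int jo = 0; jo < Wo; ++jo) {
    const int j0 = jo * stride - pad;
    for (int io = 0; io < Ho; ++io) {
      const int i0 = io * stride - pad;
      const int col = io + jo * Ho;
      for (int c = 0; c < C; ++c) {
        const arma::mat& xs = x.slice(c);
        for (int dj = 0; dj < kw; ++dj) {
          const int j = j0 + dj;
          if (j < 0 || j >= W) continue;
          for (int di = 0; di < kh; ++di) {
            const int i = i0 + di;
            if (i < 0 || i >= H) continue;
            A(di + dj * kh + c * kh * kw, col) = xs(i, j);
          }
        }
      }
    }
  }
  arma::mat out = w.t() * A;  // K x (Ho*Wo)
  arma::cube o(Ho, Wo, K);
  for (int k = 0; k < K; ++k)
    o.slice(k) = arma::reshape(out.row(k), Ho, Wo);
  return o;
}

// depthwise convolution: one kh x kw filter per channel, w is (kh*kw, C)
// [[Rcpp::export]]
arma::cube dwconv2d_fwd_cpp(const arma::cube& x, const arma::mat& w,
                            int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if ((int)w.n_rows != kh * kw || (int)w.n_cols != C)
    Rcpp::stop("dwconv2d: weight shape must be (kh*kw, C)");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::cube o(Ho, Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    arma::mat& os = o.slice(c);
    for (int jo = 0; jo < Wo; ++jo) {
      const int j0 = jo * stride - pad;
      for (int io = 0; io < Ho; ++io) {
        const int i0 = io * stride - pad;
        double acc = 0.0;
        for (int dj = 0; dj < kw; ++dj) {
          const int j = j0 + dj;
          if (j < 0 || j >= W) continue;
          for (int di = 0; di < kh; ++di) {
            const int i = i0 + di;
            if (i < 0 || i >= H) continue;
            acc += w(di + dj * kh, c) * xs(i, j);
          }
        }
        os(io, jo) = acc;
      }
    }
  }
  return o;
}
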