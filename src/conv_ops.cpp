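#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Tensors are column-major R arrays with axes (rows, cols, channels, batch).
// im2col lays one output-pixel receptive field per matrix row so that a
// same-padded KxK convolution becomes a single BLAS matmul in R:
//   out = cols %*% matrix(w, K*K*Cin, Cout)
// Row index:    h + H*w + H*W*n          (pixel within image, then batch)
// Column index: ki + K*kj + K*K*c        (matches flattening of the
//                                         (K, K, Cin, Cout) weight array)

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N, int K) {
  const int pad = (K - 1) / 2;
  const int n_rows = H * W * N;
  const int n_cols = K * K * C;
  NumericMatrix out(n_rows, n_cols);
  const double *xp = x.begin();
  double *op = out.begin();

  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const int col = ki + K * kj + K * K * c;
        double *ocol = op + (R_xlen_t)col * n_rows;
        for (int n = 0; n < N; ++n) {
          const double *xim = xp + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
          double *orow = ocol + (R_xlen_t)H * W * n;
          for (int w = 0; w < W; ++w) {
            const int src_w = w + kj - pad;
            if (src_w < 0 || src_w >= W) continue;
            const double *xcolp = xim + (R_xlen_t)H * src_w;
            double *odst = orow + (R_xlen_t)H * w;
            const int h_lo = std::max(0, pad - ki);
            const int h_hi = std::min(H, H + pad - ki);
            for (int h = h_lo; h < h_hi; ++h)
              odst[h] = xcolp[h + ki - pad];
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add of column gradients back onto the (H, W, C, N) input grid;
// the adjoint of im2col_cpp.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dcols, int H, int W, int C, int N, int K) {
  const int pad = (K - 1) / 2;
  const int n_rows = H * W * N;
  NumericVector dx((R_xlen_t)H * W * C * N);
  const double *dp = dcols.begin();
  double *xp = dx.begin();

  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const int col = ki + K * kj + K * K * c;
        const double *dcol = dp + (R_xlen_t)col * n_rows;
        for (int n = 0; n < N; ++n) {
          double *xim = xp + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
          const double *drow = dcol + (R_xlen_t)H * W * n;
          for (int w = 0; w < W; ++w) {
            const int src_w = w + kj - pad;
            if (src_w < 0 || src_w >= W) continue;
            double *xcolp = xim + (R_xlen_t)H * src_w;
            const double *dsrc = drow + (R_xlen_t)H * w;
            const int h_lo = std::max(0, pad - ki);
            const int h_hi = std::min(H, H + pad - ki);
            for (int h = h_lo; h < h_hi; ++h)
              xcolp[h + ki - pad] += dsrc[h];
          }
        }
      }
    }
  }
  return dx;
}

// 8-connected component labeling of a binary mask (stack-based flood fill).
// Labels are assigned in raster-scan discovery order, starting at 1.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (mask(h, w) == 0 || lab(h, w) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(h + H * w);
      lab(h, w) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int ph = p % H, pw = p / H;
        for (int dw = -1; dw <= 1; ++dw) {
          for (int dh = -1; dh <= 1; ++dh) {
            if (dh == 0 && dw == 0) continue;
            const int qh = ph + dh, qw = pw + dw;
            if (qh < 0 || qh >= H || qw < 0 || qw >= W) continue;
            if (mask(qh, qw) != 0 && lab(qh, qw) == 0) {
              lab(qh, qw) = next;
              stack.push_back(qh + H * qw);
            }
          }
        }
      }
    }
  }
  return lab;
}
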