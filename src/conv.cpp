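#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Tensor layout throughout: column-major array with dims (H, W, B, C), i.e.
// linear index h + H*(w + W*(b + B*c)).  Convolutions are stride-1 with
// "same" zero padding; downsampling is done by pooling layers in R.

// Unfold x into a (H*W*B) x (kh*kw*C) matrix so that a convolution becomes a
// single matrix product with a (kh*kw*C) x Cout weight matrix.  Patch column
// ordering: q = (c*kh + i)*kw + j for kernel offset (i, j) and channel c.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, IntegerVector dims, int kh, int kw) {
  const int H = dims[0], W = dims[1], B = dims[2], C = dims[3];
  const int ph = kh / 2, pw = kw / 2;
  const R_xlen_t rows = (R_xlen_t)H * W * B;
  NumericMatrix out(rows, (R_xlen_t)kh * kw * C);
  const double* X = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < kh; ++i) {
      for (int j = 0; j < kw; ++j) {
        const int col = (c * kh + i) * kw + j;
        double* O = &out(0, col);
        const int di = i - ph, dj = j - pw;
        const int h0 = std::max(0, -di), h1 = std::min(H, H - di);
        for (int b = 0; b < B; ++b) {
          const double* Xc = X + ((R_xlen_t)c * B + b) * H * W;
          double* Ob = O + (R_xlen_t)b * H * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dj;
            if (sw < 0 || sw >= W) continue;  // stays zero (padding)
            const double* Xcol = Xc + (R_xlen_t)sw * H + di;
            double* Ocol = Ob + (R_xlen_t)w * H;
            for (int h = h0; h < h1; ++h) Ocol[h] = Xcol[h];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add patch gradients back onto the input
// grid.  Used for the dX term of the convolution backward pass.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix colm, IntegerVector dims, int kh, int kw) {
  const int H = dims[0], W = dims[1], B = dims[2], C = dims[3];
  const int ph = kh / 2, pw = kw / 2;
  NumericVector out((R_xlen_t)H * W * B * C);
  double* X = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < kh; ++i) {
      for (int j = 0; j < kw; ++j) {
        const int col = (c * kh + i) * kw + j;
        const double* O = &colm(0, col);
        const int di = i - ph, dj = j - pw;
        const int h0 = std::max(0, -di), h1 = std::min(H, H - di);
        for (int b = 0; b < B; ++b) {
          double* Xc = X + ((R_xlen_t)c * B + b) * H * W;
          const double* Ob = O + (R_xlen_t)b * H * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dj;
            if (sw < 0 || sw >= W) continue;
            double* Xcol = Xc + (R_xlen_t)sw * H + di;
            const double* Ocol = Ob + (R_xlen_t)w * H;
            for (int h = h0; h < h1; ++h) Xcol[h] += Ocol[h];
          }
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Bilinear sampling of a single-channel image (H x W matrix, 0-based
// pixel-center coordinates) at arbitrary continuous positions; out-of-bounds
// reads use `fill`.
// [[Rcpp::export]]
NumericVector bilinear_sample_cpp(NumericMatrix img, NumericVector xs,
                                  NumericVector ys, double fill) {
  const int H = img.nrow(), W = img.ncol();
  const R_xlen_t n = xs.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    const double x = xs[k], y = ys[k];
    if (!R_finite(x) || !R_finite(y)) { out[k] = fill; continue; }
    const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    const double fx = x - x0, fy = y - y0;
    double v = 0.0;
    for (int dy = 0; dy <= 1; ++dy) {
      for (int dx = 0; dx <= 1; ++dx) {
        const int xi = x0 + dx, yi = y0 + dy;
        const double wgt = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy);
        const double px = (xi >= 0 && xi < W && yi >= 0 && yi < H)
                            ? img(yi, xi) : fill;
        v += wgt * px;
      }
    }
    out[k] = v;
  }
  return out;
}
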