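// Low-level kernels for the small-CNN engine: im2col/col2im lowering of
// 2D convolution (the GEMM itself runs through R's BLAS), average pooling,
// and bilinear resampling. Activation layout throughout is a dense array
// with dim (H, W, C, N), column-major, N = frames in the mini-batch.
#include <Rcpp.h>
using namespace Rcpp;

static inline int out_extent(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Lower patches to a (kh*kw*C) x (Ho*Wo*N) matrix. Row index runs fastest
// over the kernel row offset, then kernel col offset, then input channel;
// column index runs over output row, output col, frame. Out-of-image taps
// (zero padding) stay zero.
// [[Rcpp::export]]
NumericMatrix im2col_hwcn(NumericVector x, int H, int W, int C, int N,
                          int kh, int kw, int stride, int pad) {
  const int Ho = out_extent(H, kh, stride, pad);
  const int Wo = out_extent(W, kw, stride, pad);
  const int rows = kh * kw * C;
  const R_xlen_t cols = (R_xlen_t)Ho * Wo * N;
  NumericMatrix out(rows, cols);
  const double* px = x.begin();
  double* po = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t col = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        double* dst = po + col * rows;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double* src = px + ((R_xlen_t)n * C + c) * H * W;
          for (int j = 0; j < kw; ++j) {
            const int wi = w0 + j;
            for (int i = 0; i < kh; ++i) {
              const int hi = h0 + i;
              double v = 0.0;
              if (hi >= 0 && hi < H && wi >= 0 && wi < W)
                v = src[(R_xlen_t)wi * H + hi];
              dst[(c * kw + j) * kh + i] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_hwcn: scatter-add patch columns back into an
// (H, W, C, N) array (gradient w.r.t. the convolution input).
// [[Rcpp::export]]
NumericVector col2im_hwcn(NumericMatrix cols, int H, int W, int C, int N,
                          int kh, int kw, int stride, int pad) {
  const int Ho = out_extent(H, kh, stride, pad);
  const int Wo = out_extent(W, kw, stride, pad);
  const int rows = kh * kw * C;
  NumericVector x((R_xlen_t)H * W * C * N);
  double* px = x.begin();
  const double* pc = cols.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t col = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        const double* src = pc + col * rows;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          double* dst = px + ((R_xlen_t)n * C + c) * H * W;
          for (int j = 0; j < kw; ++j) {
            const int wi = w0 + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = h0 + i;
              if (hi < 0 || hi >= H) continue;
              dst[(R_xlen_t)wi * H + hi] += src[(c * kw + j) * kh + i];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// Non-overlapping-friendly average pooling, kernel k, given stride.
// [[Rcpp::export]]
NumericVector avgpool_fwd(NumericVector x, int H, int W, int C, int N,
                          int k, int stride) {
  const int Ho = (H - k) / stride + 1;
  const int Wo = (W - k) / stride + 1;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  const double inv = 1.0 / (k * k);
  const double* px = x.begin();
  double* py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = px + ((R_xlen_t)n * C + c) * H * W;
      double* dst = py + ((R_xlen_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double s = 0.0;
          for (int j = 0; j < k; ++j)
            for (int i = 0; i < k; ++i)
              s += src[(R_xlen_t)(wo * stride + j) * H + ho * stride + i];
          dst[(R_xlen_t)wo * Ho + ho] = s * inv;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool_bwd(NumericVector dy, int H, int W, int C, int N,
                          int k, int stride) {
  const int Ho = (H - k) / stride + 1;
  const int Wo = (W - k) / stride + 1;
  NumericVector dx((R_xlen_t)H * W * C * N);
  const double inv = 1.0 / (k * k);
  const double* pd = dy.begin();
  double* px = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = pd + ((R_xlen_t)n * C + c) * Ho * Wo;
      double* dst = px + ((R_xlen_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = src[(R_xlen_t)wo * Ho + ho] * inv;
          for (int j = 0; j < k; ++j)
            for (int i = 0; i < k; ++i)
              dst[(R_xlen_t)(wo * stride + j) * H + ho * stride + i] += g;
        }
    }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Bilinear resampling of a single-channel H x W matrix to Ho x Wo, with
// pixel centers aligned to the image corners (align-corners convention
// for Ho,Wo > 1). Used for frame rescaling and heatmap upsampling.
// [[Rcpp::export]]
NumericMatrix resize_bilinear(NumericMatrix img, int Ho, int Wo) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(Ho, Wo);
  const double sh = Ho > 1 ? (double)(H - 1) / (Ho - 1) : 0.0;
  const double sw = Wo > 1 ? (double)(W - 1) / (Wo - 1) : 0.0;
  for (int wo = 0; wo < Wo; ++wo) {
    const double wf = wo * sw;
    const int w0 = (int)wf;
    const int w1 = w0 + 1 < W ? w0 + 1 : w0;
    const double aw = wf - w0;
    for (int ho = 0; ho < Ho; ++ho) {
      const double hf = ho * sh;
      const int h0 = (int)hf;
      const int h1 = h0 + 1 < H ? h0 + 1 : h0;
      const double ah = hf - h0;
      out(ho, wo) =
        (1 - ah) * (1 - aw) * img(h0, w0) + ah * (1 - aw) * img(h1, w0) +
        (1 - ah) * aw * img(h0, w1) + ah * aw * img(h1, w1);
    }
  }
  return out;
}
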