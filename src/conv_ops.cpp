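// Low-level tensor kernels for the convolutional network. Activation
// tensors are column-major R arrays (H, W, C, B). All kernels write into
// caller-provided buffers: on this class of hardware the engine is bound
// by memory allocation and traffic, not arithmetic, so patch matrices
// and activation planes are recycled across iterations by the R side
// (see nn.R) and GEMMs go through BLAS.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <cstring>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// C = op(A) %*% op(B) + beta * C into a preallocated C (BLAS dgemm), so
// repeated products recycle their output storage.
// [[Rcpp::export]]
void gemm_cpp(NumericMatrix C, NumericMatrix A, NumericMatrix B,
              bool ta, bool tb, double beta) {
  const int m = ta ? A.ncol() : A.nrow();
  const int k = ta ? A.nrow() : A.ncol();
  const int kb = tb ? B.ncol() : B.nrow();
  const int n = tb ? B.nrow() : B.ncol();
  if (k != kb || C.nrow() != m || C.ncol() != n)
    stop("gemm_cpp: dimension mismatch");
  const char* TA = ta ? "T" : "N";
  const char* TB = tb ? "T" : "N";
  const double alpha = 1.0;
  const int lda = A.nrow(), ldb = B.nrow(), ldc = C.nrow();
  F77_CALL(dgemm)(TA, TB, &m, &n, &k, &alpha, A.begin(), &lda,
                  B.begin(), &ldb, &beta, C.begin(), &ldc FCONE FCONE);
}

// Fill the patch matrix P (H*W rows, kh*kw*C cols) for one image of x.
// Rows ordered (h, w) with h fastest; columns (ki, kj, c) with ki
// fastest. Out-of-range taps (zero padding) give 0. Stride-1 "same".
// [[Rcpp::export]]
void im2col_img_cpp(NumericMatrix P, NumericVector x, int H, int W, int C,
                    int img, int kh, int kw, int ph, int pw) {
  const R_xlen_t nrow = (R_xlen_t)H * W;
  const double* px = x.begin() + (R_xlen_t)img * H * W * C;
  double* pp = P.begin();
  for (int c = 0; c < C; ++c) {
    const double* plane = px + (R_xlen_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* out = pp + (R_xlen_t)(ki + kh * (kj + kw * c)) * nrow;
        for (int w = 0; w < W; ++w) {
          const int iw = w + kj - pw;
          double* dst = out + (R_xlen_t)w * H;
          if (iw < 0 || iw >= W) {
            std::memset(dst, 0, sizeof(double) * H);
            continue;
          }
          const double* srccol = plane + (R_xlen_t)iw * H;
          const int h0 = std::max(0, ph - ki);
          const int h1 = std::min(H, H + ph - ki);
          for (int h = 0; h < h0; ++h) dst[h] = 0.0;
          for (int h = h0; h < h1; ++h) dst[h] = srccol[h + ki - ph];
          for (int h = h1; h < H; ++h) dst[h] = 0.0;
        }
      }
    }
  }
}

// Adjoint of im2col_img_cpp: scatter-add the patch gradient dP into one
// image of dx, zeroing that image's block first.
// [[Rcpp::export]]
void col2im_img_cpp(NumericVector dx, NumericMatrix dP, int H, int W,
                    int C, int img, int kh, int kw, int ph, int pw) {
  const R_xlen_t nrow = (R_xlen_t)H * W;
  double* px = dx.begin() + (R_xlen_t)img * H * W * C;
  std::memset(px, 0, sizeof(double) * H * W * C);
  const double* pp = dP.begin();
  for (int c = 0; c < C; ++c) {
    double* plane = px + (R_xlen_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double* src = pp + (R_xlen_t)(ki + kh * (kj + kw * c)) * nrow;
        for (int w = 0; w < W; ++w) {
          const int iw = w + kj - pw;
          if (iw < 0 || iw >= W) continue;
          const double* s = src + (R_xlen_t)w * H;
          double* dcol = plane + (R_xlen_t)iw * H;
          const int h0 = std::max(0, ph - ki);
          const int h1 = std::min(H, H + ph - ki);
          for (int h = h0; h < h1; ++h) dcol[h + ki - ph] += s[h];
        }
      }
    }
  }
}

// Copy a (H*W x F) matrix into image `img` of a (H, W, F, B) array
// (contiguous block), adding the per-filter bias.
// [[Rcpp::export]]
void set_conv_out_cpp(NumericVector out, NumericMatrix Y, int img,
                      NumericVector bias) {
  const R_xlen_t hw = Y.nrow();
  const int F = Y.ncol();
  double* dst = out.begin() + (R_xlen_t)img * hw * F;
  const double* src = Y.begin();
  const double* b = bias.begin();
  for (int f = 0; f < F; ++f) {
    const double bf = b[f];
    const double* s = src + (R_xlen_t)f * hw;
    double* d = dst + (R_xlen_t)f * hw;
    for (R_xlen_t i = 0; i < hw; ++i) d[i] = s[i] + bf;
  }
}

// Copy image `img` of a (H, W, F, B) array into a (H*W x F) matrix.
// [[Rcpp::export]]
void get_slice_cpp(NumericMatrix Y, NumericVector x, int img) {
  const R_xlen_t n = (R_xlen_t)Y.nrow() * Y.ncol();
  std::memcpy(Y.begin(), x.begin() + (R_xlen_t)img * n, sizeof(double) * n);
}

// Per-channel sum and sum of squares over (H, W, B); one pass.
// [[Rcpp::export]]
NumericMatrix bn_stats_cpp(NumericVector x, int hw, int C, int B) {
  NumericMatrix s(2, C);
  const double* px = x.begin();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* p = px + ((R_xlen_t)b * C + c) * hw;
      double s1 = 0, s2 = 0;
      for (R_xlen_t i = 0; i < hw; ++i) { s1 += p[i]; s2 += p[i] * p[i]; }
      s(0, c) += s1;
      s(1, c) += s2;
    }
  }
  return s;
}

// y = x * A[c] + B2[c], channelwise affine (y may be the same object as x).
// [[Rcpp::export]]
void bn_affine_cpp(NumericVector y, NumericVector x, NumericVector A,
                   NumericVector B2, int hw, int C, int B) {
  const double* px = x.begin();
  double* py = y.begin();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = ((R_xlen_t)b * C + c) * hw;
      const double a = A[c], bb = B2[c];
      const double* p = px + off;
      double* q = py + off;
      for (R_xlen_t i = 0; i < hw; ++i) q[i] = p[i] * a + bb;
    }
  }
}

// Fused batch-norm backward. g is overwritten with dx; returns a 2 x C
// matrix with rows (dgamma, dbeta). x is the layer input; xhat is
// recomputed on the fly from (mu, inv_std).
// [[Rcpp::export]]
NumericMatrix bn_bwd_cpp(NumericVector g, NumericVector x, NumericVector mu,
                         NumericVector inv_std, NumericVector gamma,
                         int hw, int C, int B) {
  NumericMatrix out(2, C);
  const double* px = x.begin();
  double* pg = g.begin();
  const double n = (double)hw * B;
  std::vector<double> sg(C, 0.0), sgx(C, 0.0);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = ((R_xlen_t)b * C + c) * hw;
      const double m = mu[c], is = inv_std[c];
      const double* xp = px + off;
      const double* gp = pg + off;
      double a1 = 0, a2 = 0;
      for (R_xlen_t i = 0; i < hw; ++i) {
        a1 += gp[i];
        a2 += gp[i] * (xp[i] - m) * is;
      }
      sg[c] += a1;
      sgx[c] += a2;
    }
  }
  for (int c = 0; c < C; ++c) { out(0, c) = sgx[c]; out(1, c) = sg[c]; }
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = ((R_xlen_t)b * C + c) * hw;
      const double m = mu[c], is = inv_std[c], ga = gamma[c];
      const double c1 = sg[c] / n, c2 = sgx[c] / n;
      const double* xp = px + off;
      double* gp = pg + off;
      for (R_xlen_t i = 0; i < hw; ++i) {
        const double xh = (xp[i] - m) * is;
        gp[i] = is * ga * (gp[i] - c1 - xh * c2);
      }
    }
  }
  return out;
}

// In-place ReLU.
// [[Rcpp::export]]
void relu_cpp(NumericVector x) {
  double* p = x.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
}

// In-place ReLU backward: zero g where the forward output was zero.
// [[Rcpp::export]]
void relu_bwd_cpp(NumericVector g, NumericVector out) {
  double* pg = g.begin();
  const double* po = out.begin();
  const R_xlen_t n = g.size();
  for (R_xlen_t i = 0; i < n; ++i) if (po[i] <= 0) pg[i] = 0;
}

// Ceil-mode max pooling into preallocated out/idx (1-based argmax linear
// index into x). Output side = ceil((n - k)/s) + 1, last window clipped.
// [[Rcpp::export]]
void maxpool_fill_cpp(NumericVector out, IntegerVector idx, NumericVector x,
                      int H, int W, int C, int B, int k, int s) {
  const int Oh = (H - k + s - 1) / s + 1;
  const int Ow = (W - k + s - 1) / s + 1;
  const double* px = x.begin();
  double* po = out.begin();
  int* pi = idx.begin();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = ((R_xlen_t)b * C + c) * H * W;
      const double* img = px + base;
      const R_xlen_t obase = ((R_xlen_t)b * C + c) * Oh * Ow;
      for (int ow = 0; ow < Ow; ++ow) {
        const int w0 = ow * s, w1 = std::min(w0 + k, W);
        for (int oh = 0; oh < Oh; ++oh) {
          const int h0 = oh * s, h1 = std::min(h0 + k, H);
          double best = R_NegInf;
          R_xlen_t besti = base;
          for (int w = w0; w < w1; ++w) {
            const double* colp = img + (R_xlen_t)w * H;
            for (int h = h0; h < h1; ++h) {
              if (colp[h] > best) { best = colp[h]; besti = base + (R_xlen_t)w * H + h; }
            }
          }
          const R_xlen_t dst = obase + (R_xlen_t)ow * Oh + oh;
          po[dst] = best;
          pi[dst] = (int)(besti + 1);
        }
      }
    }
  }
}

// Scatter pooled gradients back to argmax positions; dx is zeroed first.
// [[Rcpp::export]]
void maxpool_bwd_fill_cpp(NumericVector dx, NumericVector dout,
                          IntegerVector idx) {
  std::memset(dx.begin(), 0, sizeof(double) * dx.size());
  double* p = dx.begin();
  const double* pd = dout.begin();
  const int* pi = idx.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) p[pi[i] - 1] += pd[i];
}
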