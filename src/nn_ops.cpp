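// Hot paths of the network engine: im2col/col2im for same-padded dilated
// 1D convolution and max-pooling forward/backward.  Activations are
// arrays dim (C, L, B) flattened column-major.  The *_into variants fill
// caller-owned buffers so the large temporaries are allocated once per
// layer and reused across minibatches.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
void conv_im2col_into(NumericVector x, NumericMatrix col, int C, int L,
                      int B, int k, int dil) {
  const int ke = (k - 1) * dil + 1;
  const int padL = (ke - 1) / 2;
  const double *xp = x.begin();
  double *cp = col.begin();
  const int nrow = C * k;
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < L; ++l) {
      double *dstCol = cp + (size_t)nrow * (l + (size_t)L * b);
      for (int j = 0; j < k; ++j) {
        const int src = l + j * dil - padL;
        double *dst = dstCol + j * C;
        if (src < 0 || src >= L) {
          for (int c = 0; c < C; ++c) dst[c] = 0.0;
        } else {
          const double *sp = xp + (size_t)C * (src + (size_t)L * b);
          for (int c = 0; c < C; ++c) dst[c] = sp[c];
        }
      }
    }
  }
}

// [[Rcpp::export]]
void conv_col2im_into(NumericMatrix dcol, NumericVector dx, int C, int L,
                      int B, int k, int dil) {
  const int ke = (k - 1) * dil + 1;
  const int padL = (ke - 1) / 2;
  double *xp = dx.begin();
  std::fill(xp, xp + (size_t)C * L * B, 0.0);
  const double *cp = dcol.begin();
  const int nrow = C * k;
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < L; ++l) {
      const double *srcCol = cp + (size_t)nrow * (l + (size_t)L * b);
      for (int j = 0; j < k; ++j) {
        const int src = l + j * dil - padL;
        if (src < 0 || src >= L) continue;
        double *dst = xp + (size_t)C * (src + (size_t)L * b);
        const double *sp = srcCol + j * C;
        for (int c = 0; c < C; ++c) dst[c] += sp[c];
      }
    }
  }
}

// [[Rcpp::export]]
void maxpool_fwd_into(NumericVector x, NumericVector y, IntegerVector arg,
                      int C, int L, int B, int w) {
  const int L2 = L / w;
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ap = arg.begin();
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L2; ++l)
      for (int c = 0; c < C; ++c) {
        double best = xp[c + (size_t)C * (l * w + (size_t)L * b)];
        int bi = 0;
        for (int j = 1; j < w; ++j) {
          const double v = xp[c + (size_t)C * (l * w + j + (size_t)L * b)];
          if (v > best) { best = v; bi = j; }
        }
        const size_t oi = c + (size_t)C * (l + (size_t)L2 * b);
        yp[oi] = best;
        ap[oi] = bi;
      }
}

// [[Rcpp::export]]
void maxpool_bwd_into(NumericVector dy, IntegerVector arg, NumericVector dx,
                      int C, int L, int B, int w) {
  const int L2 = L / w;
  const double *dyp = dy.begin();
  const int *ap = arg.begin();
  double *xp = dx.begin();
  std::fill(xp, xp + (size_t)C * L * B, 0.0);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < L2; ++l)
      for (int c = 0; c < C; ++c) {
        const size_t oi = c + (size_t)C * (l + (size_t)L2 * b);
        xp[c + (size_t)C * (l * w + ap[oi] + (size_t)L * b)] = dyp[oi];
      }
}
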