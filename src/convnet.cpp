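#include <Rcpp.h>
#include <vector>
#include <cstring>

using namespace Rcpp;

// Minibatch CNN kernels on channel-first arrays (C, H, W, N), column-major.
// This layout makes a (C_out x positions) GEMM result directly reshapeable
// to the activation array without any transpose.

// im2col for 3x3 'same' convolution (pad 1, stride 1).
// x: array (C, H, W, N); returns (9*C) x (H*W*N); each column holds the
// 3x3 neighbourhood of one output position, channels fastest.
// [[Rcpp::export(name = ".im2col3")]]
NumericMatrix im2col3(NumericVector x, int C, int H, int W, int N) {
  NumericMatrix out(9 * C, (R_xlen_t)H * W * N);
  const double* px = x.begin();
  double* po = out.begin();
  const long CH = (long)C * H, CHW = (long)C * H * W;
  for (int n = 0; n < N; ++n) {
    const double* img = px + n * CHW;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double* dst = po + ((long)n * H * W + (long)w * H + h) * 9 * C;
        for (int dw = -1; dw <= 1; ++dw) {
          int ww = w + dw;
          for (int dh = -1; dh <= 1; ++dh) {
            int hh = h + dh;
            if (hh >= 0 && hh < H && ww >= 0 && ww < W) {
              std::memcpy(dst, img + (long)ww * CH + (long)hh * C,
                          C * sizeof(double));
            } else {
              std::memset(dst, 0, C * sizeof(double));
            }
            dst += C;
          }
        }
      }
    }
  }
  return out;
}

// adjoint of im2col3: accumulate column gradients back into (C, H, W, N)
// [[Rcpp::export(name = ".col2im3")]]
NumericVector col2im3(NumericMatrix cols, int C, int H, int W, int N) {
  NumericVector out((R_xlen_t)C * H * W * N);
  double* po = out.begin();
  const double* pc = cols.begin();
  const long CH = (long)C * H, CHW = (long)C * H * W;
  for (int n = 0; n < N; ++n) {
    double* img = po + n * CHW;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double* src = pc + ((long)n * H * W + (long)w * H + h) * 9 * C;
        for (int dw = -1; dw <= 1; ++dw) {
          int ww = w + dw;
          for (int dh = -1; dh <= 1; ++dh) {
            int hh = h + dh;
            if (hh >= 0 && hh < H && ww >= 0 && ww < W) {
              double* dst = img + (long)ww * CH + (long)hh * C;
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
            src += C;
          }
        }
      }
    }
  }
  return out;
}

// 2x2 max pooling, stride 2, on (C, H, W, N) with even H, W; returns the
// pooled array (C, H/2, W/2, N) and 1-based argmax indices for backprop.
// [[Rcpp::export(name = ".pool2_fwd")]]
List pool2_fwd(NumericVector x, int C, int H, int W, int N) {
  int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)C * Ho * Wo * N);
  IntegerVector idx((R_xlen_t)C * Ho * Wo * N);
  const double* px = x.begin();
  const long CH = (long)C * H, CHW = (long)C * H * W;
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        long base = (long)n * CHW + (long)(2 * w) * CH + (long)(2 * h) * C;
        for (int c = 0; c < C; ++c) {
          long cand[4] = {base + c, base + c + C, base + c + CH,
                          base + c + CH + C};
          double best = px[cand[0]];
          long bi = cand[0];
          for (int k = 1; k < 4; ++k) {
            if (px[cand[k]] > best) { best = px[cand[k]]; bi = cand[k]; }
          }
          out[o] = best;
          idx[o] = (int)(bi + 1);
          ++o;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".pool2_bwd")]]
NumericVector pool2_bwd(NumericVector gout, IntegerVector idx, R_xlen_t xlen) {
  NumericVector gx(xlen);
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[idx[i] - 1] += gout[i];
  return gx;
}
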