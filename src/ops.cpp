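// Low-level numeric kernels for the tensor layer.
//
// Activation arrays are stored (C, H, W, B) with C fastest (column-major),
// so a GEMM over an im2col matrix writes output channels contiguously.
// Convolution weights are stored (C_in/groups, kh, kw, C_out).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Fill an im2col matrix for one sample and one channel group.
// col has dim (Cg * kh * kw) x (Ho * Wo); rows ordered channel-fastest.
static void im2col(const double* x, int C, int H, int W,
                   int c0, int Cg, int kh, int kw, int s, int p,
                   arma::mat& col) {
  const int Ho = out_size(H, kh, s, p), Wo = out_size(W, kw, s, p);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* dst = col.colptr(ho + Ho * wo);
      for (int kj = 0; kj < kw; ++kj) {
        int wi = wo * s - p + kj;
        for (int ki = 0; ki < kh; ++ki) {
          int hi = ho * s - p + ki;
          double* d = dst + Cg * (ki + kh * kj);
          if (hi < 0 || hi >= H || wi < 0 || wi >= W) {
            std::fill(d, d + Cg, 0.0);
          } else {
            const double* src = x + c0 + C * (hi + H * wi);
            std::copy(src, src + Cg, d);
          }
        }
      }
    }
  }
}

// Scatter-add a column matrix back onto the padded input (gradient of im2col).
static void col2im(const arma::mat& col, double* gx, int C, int H, int W,
                   int c0, int Cg, int kh, int kw, int s, int p) {
  const int Ho = out_size(H, kh, s, p), Wo = out_size(W, kw, s, p);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* src0 = col.colptr(ho + Ho * wo);
      for (int kj = 0; kj < kw; ++kj) {
        int wi = wo * s - p + kj;
        if (wi < 0 || wi >= W) continue;
        for (int ki = 0; ki < kh; ++ki) {
          int hi = ho * s - p + ki;
          if (hi < 0 || hi >= H) continue;
          const double* src = src0 + Cg * (ki + kh * kj);
          double* dst = gx + c0 + C * (hi + H * wi);
          for (int c = 0; c < Cg; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w,
                         int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], B = xd[3];
  const int Cg = wd[0], kh = wd[1], kw = wd[2], Co = wd[3];
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  const int Cog = Co / groups;
  NumericVector out(static_cast<R_xlen_t>(Co) * Ho * Wo * B);
  out.attr("dim") = IntegerVector::create(Co, Ho, Wo, B);
  arma::mat col(Cg * kh * kw, Ho * Wo);
  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + static_cast<R_xlen_t>(b) * C * H * W;
    double* ob = out.begin() + static_cast<R_xlen_t>(b) * Co * Ho * Wo;
    for (int g = 0; g < groups; ++g) {
      im2col(xb, C, H, W, g * Cg, Cg, kh, kw, stride, pad, col);
      arma::mat Wm(const_cast<double*>(w.begin()) +
                       static_cast<R_xlen_t>(g) * Cog * Cg * kh * kw,
                   Cg * kh * kw, Cog, false, true);
      arma::mat O = Wm.t() * col;  // Cog x (Ho*Wo)
      // interleave group channels into output layout
      for (int n = 0; n < Ho * Wo; ++n) {
        double* dst = ob + g * Cog + static_cast<R_xlen_t>(Co) * n;
        std::copy(O.colptr(n), O.colptr(n) + Cog, dst);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwx(NumericVector gout, NumericVector w,
                             int stride, int pad, int groups, int H, int W) {
  IntegerVector gd = gout.attr("dim"), wd = w.attr("dim");
  const int Co = gd[0], Ho = gd[1], Wo = gd[2], B = gd[3];
  const int Cg = wd[0], kh = wd[1], kw = wd[2];
  const int Cog = Co / groups, C = Cg * groups;
  NumericVector gx(static_cast<R_xlen_t>(C) * H * W * B);
  gx.attr("dim") = IntegerVector::create(C, H, W, B);
  arma::mat G(Cog, Ho * Wo);
  for (int b = 0; b < B; ++b) {
    const double* gb = gout.begin() + static_cast<R_xlen_t>(b) * Co * Ho * Wo;
    double* xb = gx.begin() + static_cast<R_xlen_t>(b) * C * H * W;
    for (int g = 0; g < groups; ++g) {
      for (int n = 0; n < Ho * Wo; ++n) {
        const double* src = gb + g * Cog + static_cast<R_xlen_t>(Co) * n;
        std::copy(src, src + Cog, G.colptr(n));
      }
      arma::mat Wm(const_cast<double*>(w.begin()) +
                       static_cast<R_xlen_t>(g) * Cog * Cg * kh * kw,
                   Cg * kh * kw, Cog, false, true);
      arma::mat col = Wm * G;  // (Cg*kh*kw) x (Ho*Wo)
      col2im(col, xb, C, H, W, g * Cg, Cg, kh, kw, stride, pad);
    }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bww(NumericVector x, NumericVector gout,
                             int kh, int kw, int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), gd = gout.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], B = xd[3];
  const int Co = gd[0], Ho = gd[1], Wo = gd[2];
  const int Cg = C / groups, Cog = Co / groups;
  NumericVector gw(static_cast<R_xlen_t>(Cg) * kh * kw * Co);
  gw.attr("dim") = IntegerVector::create(Cg, kh, kw, Co);
  arma::mat col(Cg * kh * kw, Ho * Wo);
  arma::mat G(Cog, Ho * Wo);
  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + static_cast<R_xlen_t>(b) * C * H * W;
    const double* gb = gout.begin() + static_cast<R_xlen_t>(b) * Co * Ho * Wo;
    for (int g = 0; g < groups; ++g) {
      im2col(xb, C, H, W, g * Cg, Cg, kh, kw, stride, pad, col);
      for (int n = 0; n < Ho * Wo; ++n) {
        const double* src = gb + g * Cog + static_cast<R_xlen_t>(Co) * n;
        std::copy(src, src + Cog, G.colptr(n));
      }
      arma::mat GW(gw.begin() + static_cast<R_xlen_t>(g) * Cog * Cg * kh * kw,
                   Cg * kh * kw, Cog, false, true);
      GW += col * G.t();
    }
  }
  return gw;
}

// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], B = xd[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector out(static_cast<R_xlen_t>(C) * Ho * Wo * B);
  IntegerVector idx(out.size());  // 1-based linear index into x of the max
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, B);
  for (int b = 0; b < B; ++b) {
    const R_xlen_t xoff = static_cast<R_xlen_t>(b) * C * H * W;
    const R_xlen_t ooff = static_cast<R_xlen_t>(b) * C * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c) {
          double best = -HUGE_VAL; R_xlen_t bi = -1;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              R_xlen_t xi = xoff + c + static_cast<R_xlen_t>(C) * (hi + static_cast<R_xlen_t>(H) * wi);
              if (x[xi] > best) { best = x[xi]; bi = xi; }
            }
          }
          R_xlen_t oi = ooff + c + static_cast<R_xlen_t>(C) * (ho + static_cast<R_xlen_t>(Ho) * wo);
          out[oi] = best; idx[oi] = static_cast<int>(bi) + 1;
        }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector gout, IntegerVector idx,
                             IntegerVector xdim) {
  NumericVector gx(static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[idx[i] - 1] += gout[i];
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], B = xd[3];
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector out(static_cast<R_xlen_t>(C) * Ho * Wo * B);
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, B);
  const double inv = 1.0 / (k * k);
  for (int b = 0; b < B; ++b) {
    const R_xlen_t xoff = static_cast<R_xlen_t>(b) * C * H * W;
    const R_xlen_t ooff = static_cast<R_xlen_t>(b) * C * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c) {
          double s = 0.0;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              s += x[xoff + c + static_cast<R_xlen_t>(C) * (hi + static_cast<R_xlen_t>(H) * wi)];
            }
          }
          out[ooff + c + static_cast<R_xlen_t>(C) * (ho + static_cast<R_xlen_t>(Ho) * wo)] = s * inv;
        }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bw(NumericVector gout, int k, int stride, int pad,
                             int H, int W) {
  IntegerVector gd = gout.attr("dim");
  const int C = gd[0], Ho = gd[1], Wo = gd[2], B = gd[3];
  NumericVector gx(static_cast<R_xlen_t>(C) * H * W * B);
  gx.attr("dim") = IntegerVector::create(C, H, W, B);
  const double inv = 1.0 / (k * k);
  for (int b = 0; b < B; ++b) {
    const R_xlen_t xoff = static_cast<R_xlen_t>(b) * C * H * W;
    const R_xlen_t ooff = static_cast<R_xlen_t>(b) * C * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c) {
          double g = gout[ooff + c + static_cast<R_xlen_t>(C) * (ho + static_cast<R_xlen_t>(Ho) * wo)] * inv;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              gx[xoff + c + static_cast<R_xlen_t>(C) * (hi + static_cast<R_xlen_t>(H) * wi)] += g;
            }
          }
        }
  }
  return gx;
}
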