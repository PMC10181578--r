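// Low-level dense 2-D convolution / pooling kernels.
//
// Array layout convention (shared with the R side): feature maps are
// numeric arrays with dim = c(H, W, C, B), column-major, so index
// (h, w, c, b) lives at h + H*(w + W*(c + C*b)) (0-based).
// Convolution kernels have dim = c(kh, kw, Cin/groups, Cout).
//
// Convolution is im2col + BLAS gemm per (batch, group); the backward
// pass recomputes im2col and scatters with col2im.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int k = 0; k < 4; ++k) d[k] = dm[k];
}

// Fill the im2col matrix K (kh*kw*Cg x Ho*Wo) for batch b, group g.
static void im2col(const double *x, int H, int W, int C, int b,
                   int kh, int kw, int Cg, int g0,
                   int stride, int pad, int Ho, int Wo, arma::mat &K) {
  K.zeros();
  for (int c = 0; c < Cg; ++c) {
    const double *xc = x + (size_t)(g0 + c) * H * W + (size_t)b * H * W * C;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int row = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          double *Kcol = K.colptr(0) + row; // row-strided walk
          const double *xw = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + i;
            if (hi < 0 || hi >= H) continue;
            Kcol[(size_t)(ho + Ho * wo) * K.n_rows] = xw[hi];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w,
                         NumericVector bias, int stride, int pad,
                         int groups) {
  int xd[4], wd[4];
  get_dims4(x, xd); get_dims4(w, wd);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  if (C != Cg * groups) stop("input channels do not match kernel/groups");
  if (Cout % groups != 0) stop("output channels not divisible by groups");
  const int Coutg = Cout / groups;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");
  const bool has_bias = bias.size() > 0;
  if (has_bias && (int)bias.size() != Cout) stop("bias length != out channels");

  NumericVector out((size_t)Ho * Wo * Cout * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  const int Npix = Ho * Wo;
  arma::mat K(kh * kw * Cg, Npix);

  for (int b = 0; b < B; ++b) {
    for (int g = 0; g < groups; ++g) {
      im2col(REAL(x), H, W, C, b, kh, kw, Cg, g * Cg, stride, pad, Ho, Wo, K);
      const arma::mat Wm(const_cast<double *>(REAL(w)) +
                             (size_t)g * Coutg * kh * kw * Cg,
                         kh * kw * Cg, Coutg, false, true);
      arma::mat O = Wm.t() * K; // Coutg x Npix
      for (int co = 0; co < Coutg; ++co) {
        double *op = REAL(out) +
                     (size_t)(g * Coutg + co) * Npix + (size_t)b * Npix * Cout;
        const double bb = has_bias ? bias[g * Coutg + co] : 0.0;
        for (int p = 0; p < Npix; ++p) op[p] = O(co, p) + bb;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w,
                         NumericVector dout, int stride, int pad,
                         int groups, bool need_dx, bool has_bias) {
  int xd[4], wd[4], od[4];
  get_dims4(x, xd); get_dims4(w, wd); get_dims4(dout, od);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  const int Ho = od[0], Wo = od[1];
  const int Coutg = Cout / groups;
  const int Npix = Ho * Wo;

  NumericVector dw((size_t)kh * kw * Cg * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cg, Cout);
  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = IntegerVector::create(H, W, C, B);
  NumericVector db(has_bias ? Cout : 0);

  arma::mat K(kh * kw * Cg, Npix);
  arma::mat G(Coutg, Npix);

  for (int b = 0; b < B; ++b) {
    for (int g = 0; g < groups; ++g) {
      // gather dOut for this batch/group
      for (int co = 0; co < Coutg; ++co) {
        const double *gp = REAL(dout) +
                           (size_t)(g * Coutg + co) * Npix +
                           (size_t)b * Npix * Cout;
        for (int p = 0; p < Npix; ++p) G(co, p) = gp[p];
        if (has_bias) db[g * Coutg + co] += arma::accu(G.row(co));
      }
      im2col(REAL(x), H, W, C, b, kh, kw, Cg, g * Cg, stride, pad, Ho, Wo, K);
      arma::mat dWm(REAL(dw) + (size_t)g * Coutg * kh * kw * Cg,
                    kh * kw * Cg, Coutg, false, true);
      dWm += K * G.t();
      if (need_dx) {
        const arma::mat Wm(const_cast<double *>(REAL(w)) +
                               (size_t)g * Coutg * kh * kw * Cg,
                           kh * kw * Cg, Coutg, false, true);
        arma::mat DC = Wm * G; // (kh*kw*Cg) x Npix
        // col2im scatter-add
        for (int c = 0; c < Cg; ++c) {
          double *xc = REAL(dx) + (size_t)(g * Cg + c) * H * W +
                       (size_t)b * H * W * C;
          for (int j = 0; j < kw; ++j) {
            for (int i = 0; i < kh; ++i) {
              const int row = i + kh * (j + kw * c);
              for (int wo = 0; wo < Wo; ++wo) {
                const int wi = wo * stride - pad + j;
                if (wi < 0 || wi >= W) continue;
                double *xw = xc + (size_t)wi * H;
                for (int ho = 0; ho < Ho; ++ho) {
                  const int hi = ho * stride - pad + i;
                  if (hi < 0 || hi >= H) continue;
                  xw[hi] += DC(row, ho + Ho * wo);
                }
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling, stride 1, implicit -Inf padding of pad on each side.
// Returns the pooled map and 1-based argmax indices into x.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int k, int pad) {
  int xd[4];
  get_dims4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  if (Ho < 1 || Wo < 1) stop("pooling output would be empty");
  NumericVector out((size_t)Ho * Wo * C * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector arg(out.size());
  const double *xp = REAL(x);
  double *op = REAL(out);
  size_t oi = 0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)c * H * W + (size_t)b * H * W * C;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho, ++oi) {
          double best = R_NegInf;
          size_t besti = 0;
          const int h0 = ho - pad, w0 = wo - pad;
          for (int j = std::max(0, -w0); j < std::min(k, W - w0); ++j) {
            const double *xw = xp + base + (size_t)(w0 + j) * H;
            for (int i = std::max(0, -h0); i < std::min(k, H - h0); ++i) {
              const double v = xw[h0 + i];
              if (v > best) { best = v; besti = base + (size_t)(w0 + j) * H + h0 + i; }
            }
          }
          op[oi] = best;
          arg[oi] = (int)besti + 1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dout, IntegerVector argmax,
                                   int xlen) {
  NumericVector dx(xlen);
  const double *gp = REAL(dout);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[argmax[i] - 1] += gp[i];
  return dx;
}
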