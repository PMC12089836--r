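// Compiled hot paths for the autodiff engine: grouped/dilated 2-D convolution
// (im2col + GEMM) and max pooling, on (H, W, C) column-major arrays.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad, int dil) {
  return (n + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// x: (H, W, Cin); w: (kh, kw, cin_per_group, cout); layout column-major.
// Returns list(out, col); col (the im2col buffer, all groups stacked) is
// kept only when keep_col, so the backward pass can skip rebuilding it.
// [[Rcpp::export]]
List conv2d_fw_cpp(NumericVector x, NumericVector w,
                   Nullable<NumericVector> bias,
                   int H, int W, int Cin,
                   int kh, int kw, int cout,
                   int stride, int pad_h, int pad_w, int dil, int groups,
                   bool keep_col) {
  const int cinpg = Cin / groups, coutpg = cout / groups;
  const int Ho = out_size(H, kh, stride, pad_h, dil);
  const int Wo = out_size(W, kw, stride, pad_w, dil);
  const int K = kh * kw * cinpg, L = Ho * Wo;
  NumericVector out(Ho * Wo * cout);
  NumericVector colkeep(keep_col ? (R_xlen_t)groups * K * L : 0);
  const double* xp = x.begin();
  const double* wp = w.begin();
  arma::mat col(K, L);
  for (int g = 0; g < groups; ++g) {
    // im2col for this group's input channels
    for (int ci = 0; ci < cinpg; ++ci) {
      const double* xc = xp + (size_t)(g * cinpg + ci) * H * W;
      for (int j = 0; j < kw; ++j) {
        for (int i = 0; i < kh; ++i) {
          const int r = i + kh * (j + kw * ci);
          double* cr = col.memptr() + r; // stride K across columns
          for (int ow = 0; ow < Wo; ++ow) {
            const int win = ow * stride - pad_w + j * dil;
            const bool wok = win >= 0 && win < W;
            for (int oh = 0; oh < Ho; ++oh) {
              const int hin = oh * stride - pad_h + i * dil;
              double v = 0.0;
              if (wok && hin >= 0 && hin < H) v = xc[hin + (size_t)H * win];
              cr[(size_t)K * (oh + (size_t)Ho * ow)] = v;
            }
          }
        }
      }
    }
    arma::mat Wm(coutpg, K);
    for (int co = 0; co < coutpg; ++co)
      for (int r = 0; r < K; ++r)
        Wm(co, r) = wp[r + (size_t)K * (g * coutpg + co)];
    arma::mat O = Wm * col; // (coutpg, L)
    for (int co = 0; co < coutpg; ++co) {
      double* oc = out.begin() + (size_t)(g * coutpg + co) * L;
      for (int l = 0; l < L; ++l) oc[l] = O(co, l);
    }
    if (keep_col)
      std::copy(col.memptr(), col.memptr() + (size_t)K * L,
                colkeep.begin() + (size_t)g * K * L);
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int c = 0; c < cout; ++c) {
      double* oc = out.begin() + (size_t)c * L;
      for (int l = 0; l < L; ++l) oc[l] += b[c];
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, cout);
  return List::create(_["out"] = out, _["col"] = colkeep);
}

// Gradients of conv2d w.r.t. input, weight and bias. `col_cache`, when
// non-empty, is the stacked im2col buffer saved by the forward pass.
// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericVector w, NumericVector gout,
                   int H, int W, int Cin,
                   int kh, int kw, int cout,
                   int stride, int pad_h, int pad_w, int dil, int groups,
                   bool need_gx, bool has_bias,
                   Nullable<NumericVector> col_cache) {
  const int cinpg = Cin / groups, coutpg = cout / groups;
  const int Ho = out_size(H, kh, stride, pad_h, dil);
  const int Wo = out_size(W, kw, stride, pad_w, dil);
  const int K = kh * kw * cinpg, L = Ho * Wo;
  NumericVector gx(need_gx ? x.size() : 0);
  NumericVector gw(w.size());
  NumericVector gb(has_bias ? cout : 0);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = gout.begin();
  const bool cached = col_cache.isNotNull();
  NumericVector colv;
  if (cached) colv = NumericVector(col_cache);
  arma::mat col(K, L);
  for (int g = 0; g < groups; ++g) {
    if (cached) {
      std::copy(colv.begin() + (size_t)g * K * L,
                colv.begin() + (size_t)(g + 1) * K * L, col.memptr());
    } else
    for (int ci = 0; ci < cinpg; ++ci) {
      const double* xc = xp + (size_t)(g * cinpg + ci) * H * W;
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          const int r = i + kh * (j + kw * ci);
          double* cr = col.memptr() + r;
          for (int ow = 0; ow < Wo; ++ow) {
            const int win = ow * stride - pad_w + j * dil;
            const bool wok = win >= 0 && win < W;
            for (int oh = 0; oh < Ho; ++oh) {
              const int hin = oh * stride - pad_h + i * dil;
              double v = 0.0;
              if (wok && hin >= 0 && hin < H) v = xc[hin + (size_t)H * win];
              cr[(size_t)K * (oh + (size_t)Ho * ow)] = v;
            }
          }
        }
    }
    arma::mat Gm(coutpg, L);
    for (int co = 0; co < coutpg; ++co) {
      const double* gc = gp + (size_t)(g * coutpg + co) * L;
      for (int l = 0; l < L; ++l) Gm(co, l) = gc[l];
    }
    arma::mat gWm = Gm * col.t(); // (coutpg, K)
    for (int co = 0; co < coutpg; ++co)
      for (int r = 0; r < K; ++r)
        gw[r + (size_t)K * (g * coutpg + co)] = gWm(co, r);
    if (has_bias)
      for (int co = 0; co < coutpg; ++co)
        gb[g * coutpg + co] = arma::accu(Gm.row(co));
    if (need_gx) {
      arma::mat Wm(coutpg, K);
      for (int co = 0; co < coutpg; ++co)
        for (int r = 0; r < K; ++r)
          Wm(co, r) = wp[r + (size_t)K * (g * coutpg + co)];
      arma::mat gcol = Wm.t() * Gm; // (K, L)
      for (int ci = 0; ci < cinpg; ++ci) {
        double* gxc = gx.begin() + (size_t)(g * cinpg + ci) * H * W;
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            const int r = i + kh * (j + kw * ci);
            const double* cr = gcol.memptr() + r;
            for (int ow = 0; ow < Wo; ++ow) {
              const int win = ow * stride - pad_w + j * dil;
              if (win < 0 || win >= W) continue;
              for (int oh = 0; oh < Ho; ++oh) {
                const int hin = oh * stride - pad_h + i * dil;
                if (hin < 0 || hin >= H) continue;
                gxc[hin + (size_t)H * win] +=
                  cr[(size_t)K * (oh + (size_t)Ho * ow)];
              }
            }
          }
      }
    }
  }
  if (need_gx) gx.attr("dim") = IntegerVector::create(H, W, Cin);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Max pooling with argmax bookkeeping (padding counts as -Inf).
// [[Rcpp::export]]
List maxpool_fw_cpp(NumericVector x, int H, int W, int C,
                    int k, int stride, int pad) {
  const int Ho = out_size(H, k, stride, pad, 1);
  const int Wo = out_size(W, k, stride, pad, 1);
  NumericVector out(Ho * Wo * C);
  IntegerVector idx(Ho * Wo * C); // 1-based linear index into x
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * H * W;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh) {
        double best = R_NegInf; int bi = -1;
        for (int j = 0; j < k; ++j) {
          const int win = ow * stride - pad + j;
          if (win < 0 || win >= W) continue;
          for (int i = 0; i < k; ++i) {
            const int hin = oh * stride - pad + i;
            if (hin < 0 || hin >= H) continue;
            const double v = xc[hin + (size_t)H * win];
            if (v > best) { best = v; bi = hin + H * win; }
          }
        }
        const size_t o = oh + (size_t)Ho * (ow + (size_t)Wo * c);
        out[o] = best;
        idx[o] = bi + (int)((size_t)c * H * W) + 1;
      }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bw_cpp(NumericVector gout, IntegerVector idx,
                             int H, int W, int C) {
  NumericVector gx(H * W * C);
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[idx[i] - 1] += gout[i];
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}
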