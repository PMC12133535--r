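// Low-level dense kernels for the conv-net engine.
// Array layout convention throughout: feature maps are R arrays with
// dim = c(H, W, C, N) (column-major, H fastest); conv weights have
// dim = c(kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// im2col for a single sample: col is (kh*kw*Cin) x (Ho*Wo), row index
// r = ih_k + kh*(iw_k + kw*c) so that flattened R weight arrays
// (kh,kw,Cin,Cout) multiply it directly.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   arma::mat& col) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  col.zeros(kh * kw * C, Ho * Wo);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int jk = 0; jk < kw; ++jk) {
      for (int ik = 0; ik < kh; ++ik) {
        const int r = ik + kh * (jk + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + jk;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ik;
            if (hi < 0 || hi >= H) continue;
            col(r, ho + Ho * wo) = xc[hi + (size_t)H * wi];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   double* dx) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int jk = 0; jk < kw; ++jk) {
      for (int ik = 0; ik < kh; ++ik) {
        const int r = ik + kh * (jk + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + jk;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ik;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wi] += col(r, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         Nullable<NumericVector> bias,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output would be empty");
  NumericVector y(Ho * Wo * (size_t)Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat col;
  const bool has_b = bias.isNotNull();
  arma::vec bv;
  if (has_b) {
    NumericVector b(bias);
    bv = arma::vec(b.begin(), Cout);
  }
  const size_t xs = (size_t)H * W * C, ys = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xs, H, W, C, kh, kw, stride, pad, col);
    arma::mat out(y.begin() + n * ys, (size_t)Ho * Wo, Cout, false, true);
    out = col.t() * Wm;               // (Ho*Wo) x Cout, matches y layout
    if (has_b) out.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                bool has_bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  arma::mat dWm(dw.begin(), kh * kw * Cin, Cout, false, true);
  arma::mat col;
  const size_t xs = (size_t)H * W * C, ys = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xs, H, W, C, kh, kw, stride, pad, col);
    arma::mat dYm(const_cast<double*>(dy.begin()) + n * ys,
                  (size_t)Ho * Wo, Cout, false, true);
    dWm += col * dYm;
    arma::mat dcol = Wm * dYm.t();
    col2im(dcol, H, W, C, kh, kw, stride, pad, dx.begin() + n * xs);
    if (has_bias) {
      arma::rowvec s = arma::sum(dYm, 0);
      for (int c = 0; c < Cout; ++c) db[c] += s[c];
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled values and the linear index
// (1-based, into x) of each winning element for the backward pass.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial size must be even, got %dx%d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t i00 = base + (2 * ho) + (size_t)H * (2 * wo);
          size_t best = i00;
          double v = xp[i00];
          const size_t cand[3] = {i00 + 1, i00 + H, i00 + H + 1};
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > v) { v = xp[cand[t]]; best = cand[t]; }
          // note: column-major output order is ho fastest, wo next
          size_t oi = ((size_t)n * C + c) * Ho * Wo + ho + (size_t)Ho * wo;
          y[oi] = v;
          idx[oi] = (int)(best + 1);
          (void)o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// Bilinear x2 upsampling (half-pixel centers / align_corners = FALSE).
static void up2_weights(int Ho, int H, std::vector<int>& i0,
                        std::vector<int>& i1, std::vector<double>& a) {
  i0.resize(Ho); i1.resize(Ho); a.resize(Ho);
  for (int o = 0; o < Ho; ++o) {
    double src = (o + 0.5) / 2.0 - 0.5;
    if (src < 0) src = 0;
    if (src > H - 1) src = H - 1;
    int lo = (int)std::floor(src);
    int hi = std::min(lo + 1, H - 1);
    i0[o] = lo; i1[o] = hi; a[o] = src - lo;
  }
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> r0, r1, c0, c1; std::vector<double> ra, ca;
  up2_weights(Ho, H, r0, r1, ra);
  up2_weights(Wo, W, c0, c1, ca);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* xs = xp + s * H * W;
    double* ys = yp + s * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const double b = ca[wo];
      const size_t w0 = (size_t)H * c0[wo], w1 = (size_t)H * c1[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        const double a = ra[ho];
        ys[ho + (size_t)Ho * wo] =
          (1 - a) * (1 - b) * xs[r0[ho] + w0] + a * (1 - b) * xs[r1[ho] + w0] +
          (1 - a) * b * xs[r0[ho] + w1] + a * b * xs[r1[ho] + w1];
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector dy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  std::vector<int> r0, r1, c0, c1; std::vector<double> ra, ca;
  up2_weights(Ho, H, r0, r1, ra);
  up2_weights(Wo, W, c0, c1, ca);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (size_t s = 0; s < (size_t)C * N; ++s) {
    const double* ds = dyp + s * Ho * Wo;
    double* xs = dxp + s * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      const double b = ca[wo];
      const size_t w0 = (size_t)H * c0[wo], w1 = (size_t)H * c1[wo];
      for (int ho = 0; ho < Ho; ++ho) {
        const double a = ra[ho], g = ds[ho + (size_t)Ho * wo];
        xs[r0[ho] + w0] += (1 - a) * (1 - b) * g;
        xs[r1[ho] + w0] += a * (1 - b) * g;
        xs[r0[ho] + w1] += (1 - a) * b * g;
        xs[r1[ho] + w1] += a * b * g;
      }
    }
  }
  return dx;
}

// ---- cheap elementwise / channel-axis helpers (axis 3 of (H,W,C,N)) ----

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y = clone(x);
  double* p = y.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i) if (p[i] < 0) p[i] = 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd(NumericVector g, NumericVector y) {
  NumericVector dx = clone(g);
  double* p = dx.begin();
  const double* yp = y.begin();
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (yp[i] <= 0) p[i] = 0;
  dx.attr("dim") = g.attr("dim");
  return dx;
}

// [[Rcpp::export(name = ".chan_sum")]]
NumericVector chan_sum(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector out(C);
  const double* p = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double s = 0;
      const double* q = p + ((size_t)n * C + c) * hw;
      for (size_t i = 0; i < hw; ++i) s += q[i];
      out[c] += s;
    }
  return out;
}

// y = (x - mean_c) * istd_c * gamma_c + beta_c; also returns xhat
// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd(NumericVector x, NumericVector mean, NumericVector istd,
            NumericVector gamma, NumericVector beta) {
  IntegerVector d = x.attr("dim");
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  NumericVector y(x.size()), xh(x.size());
  y.attr("dim") = d; xh.attr("dim") = d;
  const double* p = x.begin();
  double* yp = y.begin();
  double* hp = xh.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double m = mean[c], is = istd[c], g = gamma[c], b = beta[c];
      const size_t off = ((size_t)n * C + c) * hw;
      for (size_t i = 0; i < hw; ++i) {
        const double h = (p[off + i] - m) * is;
        hp[off + i] = h;
        yp[off + i] = g * h + b;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xh);
}

// dgamma_c = sum g*xhat; dbeta_c = sum g;
// training: dx = gamma*istd * (g - mean(g) - xhat*mean(g*xhat)) per channel
// eval:     dx = gamma*istd * g
// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector g, NumericVector xhat, NumericVector gamma,
            NumericVector istd, bool training) {
  IntegerVector d = g.attr("dim");
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  const double M = (double)hw * N;
  NumericVector dg(C), db(C);
  const double* gp = g.begin();
  const double* hp = xhat.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * hw;
      double s1 = 0, s2 = 0;
      for (size_t i = 0; i < hw; ++i) {
        s1 += gp[off + i];
        s2 += gp[off + i] * hp[off + i];
      }
      db[c] += s1;
      dg[c] += s2;
    }
  NumericVector dx(g.size());
  dx.attr("dim") = d;
  double* dp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double a = gamma[c] * istd[c];
      if (training) {
        const double mg = db[c] / M, mgx = dg[c] / M;
        for (size_t i = 0; i < hw; ++i)
          dp[off + i] = a * (gp[off + i] - mg - hp[off + i] * mgx);
      } else {
        for (size_t i = 0; i < hw; ++i) dp[off + i] = a * gp[off + i];
      }
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dg, _["dbeta"] = db);
}

// channel concatenation of a list of (H,W,C_k,N) arrays
// [[Rcpp::export(name = ".concat_channels")]]
NumericVector concat_channels(List xs) {
  const int K = xs.size();
  std::vector<const double*> ps(K);
  std::vector<size_t> cs(K);
  IntegerVector d0 = as<NumericVector>(xs[0]).attr("dim");
  const size_t hw = (size_t)d0[0] * d0[1];
  const int N = d0[3];
  size_t Ctot = 0;
  for (int k = 0; k < K; ++k) {
    NumericVector xk = xs[k];
    IntegerVector dk = xk.attr("dim");
    ps[k] = xk.begin();
    cs[k] = dk[2];
    Ctot += dk[2];
  }
  NumericVector y(hw * Ctot * N);
  y.attr("dim") = IntegerVector::create(d0[0], d0[1], (int)Ctot, N);
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    size_t at = 0;
    for (int k = 0; k < K; ++k) {
      const size_t len = hw * cs[k];
      std::memcpy(yp + ((size_t)n * Ctot) * hw + at,
                  ps[k] + (size_t)n * len, len * sizeof(double));
      at += len;
    }
  }
  return y;
}

// slice channels [from, to] (1-based, inclusive) out of (H,W,C,N)
// [[Rcpp::export(name = ".slice_channels")]]
NumericVector slice_channels(NumericVector x, int from, int to) {
  IntegerVector d = x.attr("dim");
  const size_t hw = (size_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  const int Cs = to - from + 1;
  NumericVector y(hw * Cs * N);
  y.attr("dim") = IntegerVector::create(d[0], d[1], Cs, N);
  const double* p = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    std::memcpy(yp + (size_t)n * Cs * hw,
                p + ((size_t)n * C + (from - 1)) * hw,
                (size_t)Cs * hw * sizeof(double));
  return y;
}

// Forward conv that also returns the im2col matrix (K x P*N) for reuse
// in the backward pass.
// [[Rcpp::export(name = ".conv2d_fwd_cache")]]
List conv2d_fwd_cache(NumericVector x, NumericVector w,
                      Nullable<NumericVector> bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  const int K = kh * kw * Cin;
  const size_t P = (size_t)Ho * Wo;
  NumericVector y(P * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  NumericMatrix colall(K, P * N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  const bool has_b = bias.isNotNull();
  arma::vec bv;
  if (has_b) {
    NumericVector b(bias);
    bv = arma::vec(b.begin(), Cout);
  }
  const size_t xs = (size_t)H * W * C, ys = P * Cout;
  for (int n = 0; n < N; ++n) {
    arma::mat col(colall.begin() + (size_t)n * K * P, K, P, false, true);
    col.zeros();
    // fill in place (same loop as im2col)
    {
      const double* xp = x.begin() + n * xs;
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + (size_t)c * H * W;
        for (int jk = 0; jk < kw; ++jk)
          for (int ik = 0; ik < kh; ++ik) {
            const int r = ik + kh * (jk + kw * c);
            for (int wo = 0; wo < Wo; ++wo) {
              const int wi = wo * stride - pad + jk;
              if (wi < 0 || wi >= W) continue;
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride - pad + ik;
                if (hi < 0 || hi >= H) continue;
                col(r, ho + (size_t)Ho * wo) = xc[hi + (size_t)H * wi];
              }
            }
          }
      }
    }
    arma::mat out(y.begin() + n * ys, P, Cout, false, true);
    out = col.t() * Wm;
    if (has_b) out.each_row() += bv.t();
  }
  return List::create(_["y"] = y, _["col"] = colall);
}

// Backward using the cached col; optionally skips dx.
// [[Rcpp::export(name = ".conv2d_bwd_cached")]]
List conv2d_bwd_cached(NumericMatrix colall, IntegerVector xdim,
                       NumericVector w, NumericVector dy, bool has_bias,
                       int stride, int pad, bool need_dx) {
  IntegerVector wd = w.attr("dim");
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  const int K = kh * kw * Cin;
  const size_t P = (size_t)Ho * Wo;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);
  NumericVector dx(need_dx ? (size_t)H * W * C * N : 0);
  if (need_dx) dx.attr("dim") = xdim;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  const size_t ys = P * Cout, xs = (size_t)H * W * C;
  for (int n = 0; n < N; ++n) {
    arma::mat col(const_cast<double*>(colall.begin()) + (size_t)n * K * P,
                  K, P, false, true);
    arma::mat dYm(const_cast<double*>(dy.begin()) + n * ys, P, Cout,
                  false, true);
    dWm += col * dYm;
    if (need_dx) {
      arma::mat dcol = Wm * dYm.t();
      col2im(dcol, H, W, C, kh, kw, stride, pad, dx.begin() + n * xs);
    }
    if (has_bias) {
      arma::rowvec s = arma::sum(dYm, 0);
      for (int c = 0; c < Cout; ++c) db[c] += s[c];
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
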