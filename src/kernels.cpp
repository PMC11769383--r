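// Compiled kernels for the tensor engine.
//
// Feature maps are R arrays with dim = c(N, C, H, W) (batch, channel,
// row, col), column-major, so element (n,c,h,w) sits at
// n + N*(c + C*(h + H*w)).  All kernels keep that layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// im2col for one sample.  Row index r = ci + Ci*(ki + kh*kj) matches the
// column-major flattening of a (Cout, Cin, kh, kw) weight array, so the
// weight array can be viewed as a Cout x K matrix without copying.
static void im2col(const double* x, int n, int N, int C, int H, int W,
                   int kh, int kw, int stride, int pad, arma::mat& col) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int j = ho + Ho * wo;
      double* cj = col.colptr(j);
      for (int kj = 0; kj < kw; ++kj) {
        const int wi = wo * stride - pad + kj;
        for (int ki = 0; ki < kh; ++ki) {
          const int hi = ho * stride - pad + ki;
          const bool in = (hi >= 0 && hi < H && wi >= 0 && wi < W);
          const int base = ki + kh * kj;
          for (int ci = 0; ci < C; ++ci) {
            cj[ci + C * base] =
                in ? x[n + (std::size_t)N * (ci + C * (hi + H * wi))] : 0.0;
          }
        }
      }
    }
  }
}

// scatter-add of a K x (Ho*Wo) gradient matrix back onto the input
static void col2im_add(const arma::mat& col, double* gx, int n, int N, int C,
                       int H, int W, int kh, int kw, int stride, int pad) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int j = ho + Ho * wo;
      const double* cj = col.colptr(j);
      for (int kj = 0; kj < kw; ++kj) {
        const int wi = wo * stride - pad + kj;
        if (wi < 0 || wi >= W) continue;
        for (int ki = 0; ki < kh; ++ki) {
          const int hi = ho * stride - pad + ki;
          if (hi < 0 || hi >= H) continue;
          const int base = ki + kh * kj;
          for (int ci = 0; ci < C; ++ci) {
            gx[n + (std::size_t)N * (ci + C * (hi + H * wi))] +=
                cj[ci + C * base];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Co = wd[0], Ci = wd[1], kh = wd[2], kw = wd[3];
  if (Ci != C) stop("conv2d: input has %d channels, kernel expects %d", C, Ci);
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  const int K = Ci * kh * kw;
  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)N * Co * Ho * Wo));
  out.attr("dim") = IntegerVector::create(N, Co, Ho, Wo);
  const arma::mat Wm(const_cast<double*>(w.begin()), Co, K, false, true);
  arma::mat col(K, Ho * Wo);
  arma::colvec bv(const_cast<double*>(b.begin()), Co, false, true);
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), n, N, C, H, W, kh, kw, stride, pad, col);
    arma::mat O = Wm * col;
    O.each_col() += bv;
    for (int j = 0; j < Ho * Wo; ++j) {
      const int ho = j % Ho, wo = j / Ho;
      const double* oj = O.colptr(j);
      for (int co = 0; co < Co; ++co)
        op[n + (std::size_t)N * (co + Co * (ho + Ho * wo))] = oj[co];
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Co = wd[0], Ci = wd[1], kh = wd[2], kw = wd[3];
  const int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  const int K = Ci * kh * kw;
  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)N * C * H * W));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = xd;
  NumericVector gw(Rf_allocVector(REALSXP, (R_xlen_t)Co * K));
  std::fill(gw.begin(), gw.end(), 0.0);
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  const arma::mat Wm(const_cast<double*>(w.begin()), Co, K, false, true);
  arma::mat gWm(gw.begin(), Co, K, false, true);
  arma::mat col(K, Ho * Wo), G(Co, Ho * Wo);
  const double* gp = gout.begin();
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < Ho * Wo; ++j) {
      const int ho = j % Ho, wo = j / Ho;
      double* gj = G.colptr(j);
      for (int co = 0; co < Co; ++co)
        gj[co] = gp[n + (std::size_t)N * (co + Co * (ho + Ho * wo))];
    }
    im2col(x.begin(), n, N, C, H, W, kh, kw, stride, pad, col);
    gWm += G * col.t();
    arma::mat gcol = Wm.t() * G;
    col2im_add(gcol, gx.begin(), n, N, C, H, W, kh, kw, stride, pad);
    for (int co = 0; co < Co; ++co) gb[co] += arma::accu(G.row(co));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// depthwise convolution, stride 1; w has dim (C, kh, kw)
// [[Rcpp::export]]
NumericVector cpp_dwconv2d_fwd(NumericVector x, NumericVector w,
                               NumericVector b, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Cw = wd[0], kh = wd[1], kw = wd[2];
  if (Cw != C)
    stop("depthwise conv: input has %d channels, kernel expects %d", C, Cw);
  const int Ho = out_size(H, kh, 1, pad), Wo = out_size(W, kw, 1, pad);
  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)N * C * Ho * Wo));
  out.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* op = out.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double acc = b[c];
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho - pad + ki;
              if (hi < 0 || hi >= H) continue;
              acc += wp[c + Cw * (ki + kh * kj)] *
                     xp[n + (std::size_t)N * (c + C * (hi + H * wi))];
            }
          }
          op[n + (std::size_t)N * (c + C * (ho + Ho * wo))] = acc;
        }
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv2d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                      int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int kh = wd[1], kw = wd[2];
  const int Ho = out_size(H, kh, 1, pad), Wo = out_size(W, kw, 1, pad);
  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)N * C * H * W));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = xd;
  NumericVector gw((R_xlen_t)C * kh * kw);
  gw.attr("dim") = wd;
  NumericVector gb(C);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = gout.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          const double g = gp[n + (std::size_t)N * (c + C * (ho + Ho * wo))];
          gb[c] += g;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = wo - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int hi = ho - pad + ki;
              if (hi < 0 || hi >= H) continue;
              const std::size_t xi =
                  n + (std::size_t)N * (c + C * (hi + H * wi));
              gw[c + C * (ki + kh * kj)] += g * xp[xi];
              gx[xi] += g * wp[c + C * (ki + kh * kj)];
            }
          }
        }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; requires even H and W
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial size (%d, %d) must be even", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)N * C * Ho * Wo));
  out.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  IntegerVector arg((R_xlen_t)N * C * Ho * Wo);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = -std::numeric_limits<double>::infinity();
          std::size_t besti = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const std::size_t xi =
                  n + (std::size_t)N *
                          (c + C * ((2 * ho + di) + H * (2 * wo + dj)));
              if (xp[xi] > best) { best = xp[xi]; besti = xi; }
            }
          const std::size_t oi =
              n + (std::size_t)N * (c + C * (ho + Ho * wo));
          op[oi] = best;
          arg[oi] = (int)besti;
        }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector gout, IntegerVector arg,
                               IntegerVector xdim) {
  NumericVector gx(Rf_allocVector(
      REALSXP, (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[arg[i]] += gout[i];
  return gx;
}

// index/weight pairs for 2x bilinear upsampling (align_corners = false):
// output position i samples input coordinate (i + 0.5)/2 - 0.5, clamped
static void up2_coeff(int n_in, std::vector<int>& i0, std::vector<int>& i1,
                      std::vector<double>& f) {
  const int n_out = 2 * n_in;
  i0.resize(n_out); i1.resize(n_out); f.resize(n_out);
  for (int i = 0; i < n_out; ++i) {
    double u = (i + 0.5) / 2.0 - 0.5;
    if (u < 0) u = 0;
    if (u > n_in - 1) u = n_in - 1;
    int a = (int)std::floor(u);
    if (a > n_in - 2) a = n_in - 2;
    if (a < 0) a = 0;
    i0[i] = a;
    i1[i] = (n_in == 1) ? 0 : a + 1;
    f[i] = (n_in == 1) ? 0.0 : u - a;
  }
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> rf, cf;
  up2_coeff(H, r0, r1, rf);
  up2_coeff(W, c0, c1, cf);
  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)N * C * Ho * Wo));
  out.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  const double* xp = x.begin();
  double* op = out.begin();
  const int NC = N * C;
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      const double fr = rf[ho], fc = cf[wo];
      const double w00 = (1 - fr) * (1 - fc), w01 = (1 - fr) * fc,
                   w10 = fr * (1 - fc), w11 = fr * fc;
      const std::size_t b00 = (std::size_t)NC * (r0[ho] + H * c0[wo]);
      const std::size_t b01 = (std::size_t)NC * (r0[ho] + H * c1[wo]);
      const std::size_t b10 = (std::size_t)NC * (r1[ho] + H * c0[wo]);
      const std::size_t b11 = (std::size_t)NC * (r1[ho] + H * c1[wo]);
      double* o = op + (std::size_t)NC * (ho + Ho * wo);
      for (int k = 0; k < NC; ++k)
        o[k] = w00 * xp[b00 + k] + w01 * xp[b01 + k] + w10 * xp[b10 + k] +
               w11 * xp[b11 + k];
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gout, IntegerVector xdim) {
  const int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> rf, cf;
  up2_coeff(H, r0, r1, rf);
  up2_coeff(W, c0, c1, cf);
  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)N * C * H * W));
  std::fill(gx.begin(), gx.end(), 0.0);
  gx.attr("dim") = xdim;
  const double* gp = gout.begin();
  double* xp = gx.begin();
  const int NC = N * C;
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      const double fr = rf[ho], fc = cf[wo];
      const double w00 = (1 - fr) * (1 - fc), w01 = (1 - fr) * fc,
                   w10 = fr * (1 - fc), w11 = fr * fc;
      const std::size_t b00 = (std::size_t)NC * (r0[ho] + H * c0[wo]);
      const std::size_t b01 = (std::size_t)NC * (r0[ho] + H * c1[wo]);
      const std::size_t b10 = (std::size_t)NC * (r1[ho] + H * c0[wo]);
      const std::size_t b11 = (std::size_t)NC * (r1[ho] + H * c1[wo]);
      const double* g = gp + (std::size_t)NC * (ho + Ho * wo);
      for (int k = 0; k < NC; ++k) {
        xp[b00 + k] += w00 * g[k];
        xp[b01 + k] += w01 * g[k];
        xp[b10 + k] += w10 * g[k];
        xp[b11 + k] += w11 * g[k];
      }
    }
  return gx;
}

// exact 1-D squared distance transform (lower envelope of parabolas)
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// exact Euclidean distance (pixel units) from every pixel to the nearest
// nonzero pixel of `seed`; all-zero map when `seed` is empty
// [[Rcpp::export]]
NumericMatrix cpp_edt(NumericMatrix seed) {
  const int H = seed.nrow(), W = seed.ncol();
  const double BIG = 1e20;
  bool any = false;
  NumericMatrix d2(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      d2(i, j) = seed(i, j) != 0 ? 0.0 : BIG;
      if (seed(i, j) != 0) any = true;
    }
  NumericMatrix out(H, W);
  if (!any) return out;
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int j = 0; j < W; ++j) {  // columns first (contiguous)
    for (int i = 0; i < H; ++i) f[i] = d2(i, j);
    dt1d(f, d, H);
    for (int i = 0; i < H; ++i) d2(i, j) = d[i];
  }
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = d2(i, j);
    dt1d(f, d, W);
    for (int j = 0; j < W; ++j) out(i, j) = std::sqrt(d[j]);
  }
  return out;
}
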