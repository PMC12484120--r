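// Hot elementwise / reduction kernels for (batch, channel, row, col) arrays,
// layout n + N*(c + C*(h + H*w)). Loops keep the batch axis innermost so all
// inner accesses are contiguous.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void dims4(const NumericVector& x, int& N, int& C, int& H, int& W) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a rank-4 array");
  N = d[0]; C = d[1]; H = d[2]; W = d[3];
}

// [[Rcpp::export(name = ".relu_fw")]]
NumericVector relu_fw(NumericVector x) {
  NumericVector y(Rcpp::no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export(name = ".relu_bw")]]
NumericVector relu_bw(NumericVector g, NumericVector x) {
  NumericVector gx(Rcpp::no_init(g.size()));
  gx.attr("dim") = g.attr("dim");
  const double* gp = g.begin();
  const double* xp = x.begin();
  double* op = gx.begin();
  const R_xlen_t n = g.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = xp[i] > 0 ? gp[i] : 0.0;
  return gx;
}

// y = x * a[c] + b[c] (per-channel affine; batch norm forward/normalize).
// [[Rcpp::export(name = ".chan_affine")]]
NumericVector chan_affine(NumericVector x, NumericVector a, NumericVector b) {
  int N, C, H, W;
  dims4(x, N, C, H, W);
  NumericVector y(Rcpp::no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  const int P = H * W;
  for (int p = 0; p < P; ++p) {
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c];
      const std::size_t off = (std::size_t)N * (c + (std::size_t)C * p);
      for (int n = 0; n < N; ++n) yp[off + n] = xp[off + n] * ac + bc;
    }
  }
  return y;
}

// dx = g * a1[c] + h * a2[c] + a3[c] (batch norm backward, fused).
// [[Rcpp::export(name = ".chan_affine2")]]
NumericVector chan_affine2(NumericVector g, NumericVector h, NumericVector a1,
                           NumericVector a2, NumericVector a3) {
  int N, C, H, W;
  dims4(g, N, C, H, W);
  NumericVector y(Rcpp::no_init(g.size()));
  y.attr("dim") = g.attr("dim");
  const double* gp = g.begin();
  const double* hp = h.begin();
  double* yp = y.begin();
  const int P = H * W;
  for (int p = 0; p < P; ++p) {
    for (int c = 0; c < C; ++c) {
      const double u = a1[c], v = a2[c], w = a3[c];
      const std::size_t off = (std::size_t)N * (c + (std::size_t)C * p);
      for (int n = 0; n < N; ++n) yp[off + n] = gp[off + n] * u + hp[off + n] * v + w;
    }
  }
  return y;
}

// Per-channel sum over (batch, row, col).
// [[Rcpp::export(name = ".chan_sum")]]
NumericVector chan_sum(NumericVector x) {
  int N, C, H, W;
  dims4(x, N, C, H, W);
  NumericVector s(C);
  const double* xp = x.begin();
  const int P = H * W;
  for (int p = 0; p < P; ++p) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)N * (c + (std::size_t)C * p);
      double acc = 0;
      for (int n = 0; n < N; ++n) acc += xp[off + n];
      s[c] += acc;
    }
  }
  return s;
}

// Per-channel sum of x*y.
// [[Rcpp::export(name = ".chan_dot")]]
NumericVector chan_dot(NumericVector x, NumericVector y) {
  int N, C, H, W;
  dims4(x, N, C, H, W);
  NumericVector s(C);
  const double* xp = x.begin();
  const double* yp = y.begin();
  const int P = H * W;
  for (int p = 0; p < P; ++p) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)N * (c + (std::size_t)C * p);
      double acc = 0;
      for (int n = 0; n < N; ++n) acc += xp[off + n] * yp[off + n];
      s[c] += acc;
    }
  }
  return s;
}

// Channel-wise mean and max maps; argmax stored as 1-based channel index.
// [[Rcpp::export(name = ".cmaps_fw")]]
List cmaps_fw(NumericVector x) {
  int N, C, H, W;
  dims4(x, N, C, H, W);
  const int P = H * W;
  NumericVector mean(Rcpp::no_init((std::size_t)N * P));
  NumericVector mx(Rcpp::no_init((std::size_t)N * P));
  IntegerVector am(Rcpp::no_init((std::size_t)N * P));
  mean.attr("dim") = IntegerVector::create(N, 1, H, W);
  mx.attr("dim") = IntegerVector::create(N, 1, H, W);
  const double* xp = x.begin();
  for (int p = 0; p < P; ++p) {
    for (int n = 0; n < N; ++n) {
      const std::size_t base = n + (std::size_t)N * (std::size_t)C * p;
      double acc = 0, best = xp[base];
      int bi = 1;
      for (int c = 0; c < C; ++c) {
        const double v = xp[base + (std::size_t)N * c];
        acc += v;
        if (v > best) { best = v; bi = c + 1; }
      }
      const std::size_t o = n + (std::size_t)N * p;
      mean[o] = acc / C;
      mx[o] = best;
      am[o] = bi;
    }
  }
  return List::create(_["mean"] = mean, _["max"] = mx, _["argmax"] = am);
}

// Backward of the stacked mean/max maps in one pass.
// [[Rcpp::export(name = ".cmaps_bw")]]
NumericVector cmaps_bw(NumericVector gmean, NumericVector gmax, IntegerVector am, int C) {
  IntegerVector d = gmean.attr("dim");
  const int N = d[0], H = d[2], W = d[3];
  const int P = H * W;
  NumericVector gx((std::size_t)N * C * P);
  gx.attr("dim") = IntegerVector::create(N, C, H, W);
  double* gp = gx.begin();
  const double* gm = gmean.begin();
  const double* gM = gmax.begin();
  for (int p = 0; p < P; ++p) {
    for (int n = 0; n < N; ++n) {
      const std::size_t o = n + (std::size_t)N * p;
      const double share = gm[o] / C;
      const std::size_t base = n + (std::size_t)N * (std::size_t)C * p;
      for (int c = 0; c < C; ++c) gp[base + (std::size_t)N * c] += share;
      gp[base + (std::size_t)N * (am[o] - 1)] += gM[o];
    }
  }
  return gx;
}

// y = x * w with w (N, 1, H, W) broadcast over channels.
// [[Rcpp::export(name = ".sscale_fw")]]
NumericVector sscale_fw(NumericVector x, NumericVector w) {
  int N, C, H, W;
  dims4(x, N, C, H, W);
  NumericVector y(Rcpp::no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  const int P = H * W;
  for (int p = 0; p < P; ++p) {
    const double* wrow = wp + (std::size_t)N * p;
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)N * (c + (std::size_t)C * p);
      for (int n = 0; n < N; ++n) yp[off + n] = xp[off + n] * wrow[n];
    }
  }
  return y;
}

// Channel-sum of g*x -> (N, 1, H, W) (gradient w.r.t. spatial weights).
// [[Rcpp::export(name = ".sscale_gw")]]
NumericVector sscale_gw(NumericVector g, NumericVector x) {
  int N, C, H, W;
  dims4(x, N, C, H, W);
  const int P = H * W;
  NumericVector gw((std::size_t)N * P);
  gw.attr("dim") = IntegerVector::create(N, 1, H, W);
  const double* gp = g.begin();
  const double* xp = x.begin();
  double* wp = gw.begin();
  for (int p = 0; p < P; ++p) {
    double* wrow = wp + (std::size_t)N * p;
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)N * (c + (std::size_t)C * p);
      for (int n = 0; n < N; ++n) wrow[n] += gp[off + n] * xp[off + n];
    }
  }
  return gw;
}

// Global average pool -> (N, C) matrix.
// [[Rcpp::export(name = ".gap_fw")]]
NumericMatrix gap_fw(NumericVector x) {
  int N, C, H, W;
  dims4(x, N, C, H, W);
  NumericMatrix y(N, C);
  const double* xp = x.begin();
  const int P = H * W;
  for (int p = 0; p < P; ++p) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)N * (c + (std::size_t)C * p);
      for (int n = 0; n < N; ++n) y(n, c) += xp[off + n];
    }
  }
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) y(n, c) /= P;
  return y;
}

// Global max pool -> (N, C) values and 1-based flat pixel argmax.
// [[Rcpp::export(name = ".gmp_fw")]]
List gmp_fw(NumericVector x) {
  int N, C, H, W;
  dims4(x, N, C, H, W);
  NumericMatrix y(N, C);
  IntegerMatrix am(N, C);
  const double* xp = x.begin();
  const int P = H * W;
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      double best = xp[n + (std::size_t)N * c];
      int bi = 1;
      for (int p = 0; p < P; ++p) {
        const double v = xp[n + (std::size_t)N * (c + (std::size_t)C * p)];
        if (v > best) { best = v; bi = p + 1; }
      }
      y(n, c) = best;
      am(n, c) = bi;
    }
  }
  return List::create(_["value"] = y, _["argmax"] = am);
}

// Separable resampling y = A x B^T applied per (n, c) image.
// [[Rcpp::export(name = ".resize_hw")]]
NumericVector resize_hw(NumericVector x, NumericMatrix A, NumericMatrix B) {
  int N, C, H, W;
  dims4(x, N, C, H, W);
  const int Hp = A.nrow(), Wp = B.nrow();
  if (A.ncol() != H || B.ncol() != W) stop("resize matrix extents mismatch");
  arma::mat Am(A.begin(), Hp, H, false, true);
  arma::mat Bm(B.begin(), Wp, W, false, true);
  NumericVector y(Rcpp::no_init((std::size_t)N * C * Hp * Wp));
  y.attr("dim") = IntegerVector::create(N, C, Hp, Wp);
  const double* xp = x.begin();
  double* yp = y.begin();
  arma::mat M(H, W), T1, T2;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          M(h, w) = xp[n + (std::size_t)N * (c + (std::size_t)C * (h + (std::size_t)H * w))];
      T1 = Am * M;
      T2 = T1 * Bm.t();
      for (int w = 0; w < Wp; ++w)
        for (int h = 0; h < Hp; ++h)
          yp[n + (std::size_t)N * (c + (std::size_t)C * (h + (std::size_t)Hp * w))] = T2(h, w);
    }
  }
  return y;
}

// y = x * w with w a per-(batch, channel) gate (N, C, 1, 1).
// [[Rcpp::export(name = ".nc_scale")]]
NumericVector nc_scale(NumericVector x, NumericVector w) {
  int N, C, H, W;
  dims4(x, N, C, H, W);
  NumericVector y(Rcpp::no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  const double* wp = w.begin(); // length N*C, layout (n, c)
  double* yp = y.begin();
  const int P = H * W;
  const std::size_t NC = (std::size_t)N * C;
  for (int p = 0; p < P; ++p) {
    const std::size_t off = NC * p;
    for (std::size_t i = 0; i < NC; ++i) yp[off + i] = xp[off + i] * wp[i];
  }
  return y;
}

// Per-(batch, channel) sum of g*x -> (N, C, 1, 1) gate gradient.
// [[Rcpp::export(name = ".nc_dot")]]
NumericVector nc_dot(NumericVector g, NumericVector x) {
  int N, C, H, W;
  dims4(x, N, C, H, W);
  NumericVector s((std::size_t)N * C);
  s.attr("dim") = IntegerVector::create(N, C, 1, 1);
  const double* gp = g.begin();
  const double* xp = x.begin();
  double* sp = s.begin();
  const int P = H * W;
  const std::size_t NC = (std::size_t)N * C;
  for (int p = 0; p < P; ++p) {
    const std::size_t off = NC * p;
    for (std::size_t i = 0; i < NC; ++i) sp[i] += gp[off + i] * xp[off + i];
  }
  return s;
}

// Fused epilogue of the conv->batchnorm->relu unit. Given the convolution
// output z (modified in place to hold xhat), per-channel statistics are
// computed and y = relu(gamma*xhat + beta) returned.
// [[Rcpp::export(name = ".bnrelu_fw")]]
List bnrelu_fw(NumericVector z, NumericVector gamma, NumericVector beta,
               double eps, bool training, NumericVector rmean, NumericVector rvar) {
  int N, C, H, W;
  dims4(z, N, C, H, W);
  const int P = H * W;
  const double M = (double)N * P;
  NumericVector mu(C), var(C), inv(C);
  double* zp = z.begin();
  if (training) {
    for (int p = 0; p < P; ++p) {
      for (int c = 0; c < C; ++c) {
        const std::size_t off = (std::size_t)N * (c + (std::size_t)C * p);
        double s = 0, s2 = 0;
        for (int n = 0; n < N; ++n) { const double v = zp[off + n]; s += v; s2 += v * v; }
        mu[c] += s; var[c] += s2;
      }
    }
    for (int c = 0; c < C; ++c) {
      mu[c] /= M;
      var[c] = std::max(var[c] / M - mu[c] * mu[c], 0.0);
      inv[c] = 1.0 / std::sqrt(var[c] + eps);
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = rmean[c];
      var[c] = rvar[c];
      inv[c] = 1.0 / std::sqrt(rvar[c] + eps);
    }
  }
  NumericVector y(Rcpp::no_init(z.size()));
  y.attr("dim") = z.attr("dim");
  double* yp = y.begin();
  for (int p = 0; p < P; ++p) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)N * (c + (std::size_t)C * p);
      const double m = mu[c], iv = inv[c], ga = gamma[c], be = beta[c];
      for (int n = 0; n < N; ++n) {
        const double xh = (zp[off + n] - m) * iv;
        zp[off + n] = xh; // z now holds xhat
        const double a = ga * xh + be;
        yp[off + n] = a > 0 ? a : 0.0;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = z, _["mu"] = mu, _["var"] = var,
                      _["inv"] = inv);
}

// Fused backward of batchnorm+relu: returns dz (gradient w.r.t. the
// convolution output) plus dgamma/dbeta. Training-mode statistics coupling.
// [[Rcpp::export(name = ".bnrelu_bw")]]
List bnrelu_bw(NumericVector g, NumericVector y, NumericVector xhat,
               NumericVector gamma, NumericVector inv, bool training) {
  int N, C, H, W;
  dims4(g, N, C, H, W);
  const int P = H * W;
  const double M = (double)N * P;
  NumericVector dz(Rcpp::no_init(g.size()));
  dz.attr("dim") = g.attr("dim");
  NumericVector dgamma(C), dbeta(C);
  const double* gp = g.begin();
  const double* yp = y.begin();
  const double* xp = xhat.begin();
  double* dp = dz.begin();
  // pass 1: masked gradient (store g*relu' in dz) and channel sums
  for (int p = 0; p < P; ++p) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)N * (c + (std::size_t)C * p);
      double s1 = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double gr = yp[off + n] > 0 ? gp[off + n] : 0.0;
        dp[off + n] = gr;
        s1 += gr;
        s2 += gr * xp[off + n];
      }
      dbeta[c] += s1;
      dgamma[c] += s2;
    }
  }
  // pass 2: dz = inv/M * (M*gamma*gr - gamma*dbeta - xhat*gamma*dgamma)
  for (int p = 0; p < P; ++p) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)N * (c + (std::size_t)C * p);
      const double gi = gamma[c] * inv[c];
      if (training) {
        const double t1 = gi * dbeta[c] / M, t2 = gi * dgamma[c] / M;
        for (int n = 0; n < N; ++n)
          dp[off + n] = dp[off + n] * gi - t1 - xp[off + n] * t2;
      } else {
        for (int n = 0; n < N; ++n) dp[off + n] *= gi;
      }
    }
  }
  return List::create(_["dz"] = dz, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Nearest-neighbour 2x upsampling (pixel duplication).
// [[Rcpp::export(name = ".up2_nearest")]]
NumericVector up2_nearest(NumericVector x) {
  int N, C, H, W;
  dims4(x, N, C, H, W);
  NumericVector y(Rcpp::no_init(4 * x.size()));
  y.attr("dim") = IntegerVector::create(N, C, 2 * H, 2 * W);
  const double* xp = x.begin();
  double* yp = y.begin();
  const std::size_t NC = (std::size_t)N * C;
  for (int w = 0; w < 2 * W; ++w) {
    const int iw = w / 2;
    for (int h = 0; h < 2 * H; ++h) {
      const int ih = h / 2;
      const double* s = xp + NC * (ih + (std::size_t)H * iw);
      double* d = yp + NC * (h + (std::size_t)2 * H * w);
      std::copy(s, s + NC, d);
    }
  }
  return y;
}

// Exact 2x2 box-average downsampling (area interpolation for even extents).
// [[Rcpp::export(name = ".down2_area")]]
NumericVector down2_area(NumericVector x) {
  int N, C, H, W;
  dims4(x, N, C, H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Rcpp::no_init((std::size_t)N * C * Ho * Wo));
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  const double* xp = x.begin();
  double* yp = y.begin();
  const std::size_t NC = (std::size_t)N * C;
  for (int w = 0; w < Wo; ++w) {
    for (int h = 0; h < Ho; ++h) {
      const double* s00 = xp + NC * (2 * h + (std::size_t)H * (2 * w));
      const double* s10 = s00 + NC;
      const double* s01 = xp + NC * (2 * h + (std::size_t)H * (2 * w + 1));
      const double* s11 = s01 + NC;
      double* d = yp + NC * (h + (std::size_t)Ho * w);
      for (std::size_t i = 0; i < NC; ++i)
        d[i] = 0.25 * (s00[i] + s10[i] + s01[i] + s11[i]);
    }
  }
  return y;
}

// Half-pixel-centre bilinear 2x upsampling, separable 0.75/0.25 stencil.
// [[Rcpp::export(name = ".up2_bilinear")]]
NumericVector up2_bilinear(NumericVector x) {
  int N, C, H, W;
  dims4(x, N, C, H, W);
  const std::size_t NC = (std::size_t)N * C;
  // expand rows: (N, C, 2H, W)
  std::vector<double> tmp(NC * 2 * H * W);
  const double* xp = x.begin();
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < 2 * H; ++h) {
      const int j = h / 2;
      int j0, j1; double f0, f1;
      if (h % 2 == 0) { j0 = j > 0 ? j - 1 : 0; j1 = j; f0 = 0.25; f1 = 0.75; }
      else { j0 = j; j1 = j < H - 1 ? j + 1 : H - 1; f0 = 0.75; f1 = 0.25; }
      const double* s0 = xp + NC * (j0 + (std::size_t)H * w);
      const double* s1 = xp + NC * (j1 + (std::size_t)H * w);
      double* d = tmp.data() + NC * (h + (std::size_t)2 * H * w);
      for (std::size_t i = 0; i < NC; ++i) d[i] = f0 * s0[i] + f1 * s1[i];
    }
  }
  // expand columns: (N, C, 2H, 2W)
  NumericVector y(Rcpp::no_init(NC * 4 * H * W));
  y.attr("dim") = IntegerVector::create(N, C, 2 * H, 2 * W);
  double* yp = y.begin();
  const std::size_t colsz = NC * 2 * H;
  for (int w = 0; w < 2 * W; ++w) {
    const int j = w / 2;
    int j0, j1; double f0, f1;
    if (w % 2 == 0) { j0 = j > 0 ? j - 1 : 0; j1 = j; f0 = 0.25; f1 = 0.75; }
    else { j0 = j; j1 = j < W - 1 ? j + 1 : W - 1; f0 = 0.75; f1 = 0.25; }
    const double* s0 = tmp.data() + colsz * j0;
    const double* s1 = tmp.data() + colsz * j1;
    double* d = yp + colsz * w;
    for (std::size_t i = 0; i < colsz; ++i) d[i] = f0 * s0[i] + f1 * s1[i];
  }
  return y;
}

// Channel concatenation of a list of (N, Ck, H, W) arrays.
// [[Rcpp::export(name = ".concat_c")]]
NumericVector concat_c(List xs) {
  const int K = xs.size();
  std::vector<const double*> ps(K);
  std::vector<int> cs(K);
  int N = 0, H = 0, W = 0, Ct = 0;
  for (int k = 0; k < K; ++k) {
    NumericVector x = xs[k];
    IntegerVector d = x.attr("dim");
    if (k == 0) { N = d[0]; H = d[2]; W = d[3]; }
    ps[k] = REAL(x);
    cs[k] = d[1];
    Ct += d[1];
  }
  NumericVector y(Rcpp::no_init((std::size_t)N * Ct * H * W));
  y.attr("dim") = IntegerVector::create(N, Ct, H, W);
  double* yp = y.begin();
  const int P = H * W;
  for (int p = 0; p < P; ++p) {
    double* dst = yp + (std::size_t)N * Ct * p;
    for (int k = 0; k < K; ++k) {
      const std::size_t blk = (std::size_t)N * cs[k];
      std::copy(ps[k] + blk * p, ps[k] + blk * (p + 1), dst);
      dst += blk;
    }
  }
  return y;
}

// Split the channel axis back into blocks of sizes cs (concat backward).
// [[Rcpp::export(name = ".split_c")]]
List split_c(NumericVector g, IntegerVector cs) {
  IntegerVector d = g.attr("dim");
  const int N = d[0], Ct = d[1], H = d[2], W = d[3];
  const int K = cs.size();
  List out(K);
  std::vector<double*> ps(K);
  for (int k = 0; k < K; ++k) {
    NumericVector o(Rcpp::no_init((std::size_t)N * cs[k] * H * W));
    o.attr("dim") = IntegerVector::create(N, cs[k], H, W);
    ps[k] = o.begin();
    out[k] = o;
  }
  const double* gp = g.begin();
  const int P = H * W;
  for (int p = 0; p < P; ++p) {
    const double* src = gp + (std::size_t)N * Ct * p;
    for (int k = 0; k < K; ++k) {
      const std::size_t blk = (std::size_t)N * cs[k];
      std::copy(src, src + blk, ps[k] + blk * p);
      src += blk;
    }
  }
  return out;
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// Keep large transient tensor allocations on the heap instead of mmap so the
// pages are recycled across autodiff steps (avoids repeated zero-fill faults).
// [[Rcpp::export(name = ".tune_allocator")]]
void tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}
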