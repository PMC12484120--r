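// Dilated 2-D convolution kernels (stride 1, zero "same" padding, odd kernels).
// Tensor layout follows the package contract (batch, channel, row, col) stored
// column-major, i.e. element (n, c, h, w) sits at n + N*(c + C*(h + H*w)).
// Weights are (kh, kw, cin, cout).
//
// im2col + GEMM, tiled over strips of image columns so the column matrix
// stays cache-resident even for wide feature maps; the batch axis is
// innermost in memory, so every copy moves N contiguous doubles. Backward
// recomputes the column strips instead of caching them, trading a little CPU
// for tape memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& N, int& C, int& H, int& W) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a rank-4 array (batch, channel, row, col)");
  N = d[0]; C = d[1]; H = d[2]; W = d[3];
}

// Strip width keeping N*H*ws*K doubles within ~768 KB of cache.
static inline int strip_width(int N, int H, int K, int W) {
  const double target = 98304.0; // doubles
  int ws = (int)(target / ((double)N * H * K));
  if (ws < 1) ws = 1;
  if (ws > W) ws = W;
  return ws;
}

// Fill cols ((N*H*ws) x K) for image columns [w0, w0+ws). Column index
// r = ki + kh*(kj + kw*c) matches the column-major flattening of the
// (kh, kw, cin, cout) weight array; row n + N*(h + H*(w-w0)) matches the
// activation layout for fixed channel.
static void im2col_strip(const double* x, int N, int C, int H, int W,
                         int kh, int kw, int dil, int w0, int ws,
                         int c0, int c1, arma::mat& cols) {
  const int ph = (kh - 1) * dil / 2, pw = (kw - 1) * dil / 2;
  for (int c = c0; c < c1; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* dst = cols.colptr(ki + kh * (kj + kw * (c - c0)));
        for (int wl = 0; wl < ws; ++wl) {
          const int iw = w0 + wl - pw + kj * dil;
          double* dcol = dst + (std::size_t)N * H * wl;
          if (iw < 0 || iw >= W) {
            std::fill(dcol, dcol + (std::size_t)N * H, 0.0);
            continue;
          }
          const double* xcol = x + (std::size_t)N * (c + (std::size_t)C * (std::size_t)H * iw);
          for (int h = 0; h < H; ++h) {
            const int ih = h - ph + ki * dil;
            double* d2 = dcol + (std::size_t)N * h;
            if (ih < 0 || ih >= H) {
              std::fill(d2, d2 + N, 0.0);
            } else {
              const double* s2 = xcol + (std::size_t)N * C * ih;
              std::copy(s2, s2 + N, d2);
            }
          }
        }
      }
    }
  }
}

// Scatter-add a ((N*H*ws) x K) strip back into the gradient image.
static void col2im_strip(const arma::mat& cols, int N, int C, int H, int W,
                         int kh, int kw, int dil, int w0, int ws,
                         int c0, int c1, double* gx) {
  const int ph = (kh - 1) * dil / 2, pw = (kw - 1) * dil / 2;
  for (int c = c0; c < c1; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double* src = cols.colptr(ki + kh * (kj + kw * (c - c0)));
        for (int wl = 0; wl < ws; ++wl) {
          const int iw = w0 + wl - pw + kj * dil;
          if (iw < 0 || iw >= W) continue;
          const double* scol = src + (std::size_t)N * H * wl;
          double* gcol = gx + (std::size_t)N * (c + (std::size_t)C * (std::size_t)H * iw);
          for (int h = 0; h < H; ++h) {
            const int ih = h - ph + ki * dil;
            if (ih < 0 || ih >= H) continue;
            const double* s2 = scol + (std::size_t)N * h;
            double* d2 = gcol + (std::size_t)N * C * ih;
            for (int n = 0; n < N; ++n) d2[n] += s2[n];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector wgt, NumericVector bias, int dil) {
  int N, C, H, W;
  get_dims4(x, N, C, H, W);
  IntegerVector wd = wgt.attr("dim");
  if (wd.size() != 4) stop("weights must be (kh, kw, cin, cout)");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  if (cin != C) stop("input has %d channels but weights expect %d", C, cin);
  if (kh % 2 == 0 || kw % 2 == 0) stop("kernel extents must be odd");

  const int K = kh * kw * cin;
  arma::mat Wm(const_cast<double*>(wgt.begin()), K, cout, false, true);
  // channel blocking keeps each column chunk within ~384 KB
  int cb = std::max(1, (int)(49152.0 / ((double)N * H * kh * kw)));
  if (cb > C) cb = C;
  const int Kb = kh * kw * cb;
  const int ws = strip_width(N, H, Kb, W);
  arma::mat cols((std::size_t)N * H * ws, Kb);
  arma::mat Y;

  NumericVector out(Rcpp::no_init((std::size_t)N * cout * H * W));
  out.attr("dim") = IntegerVector::create(N, cout, H, W);
  double* op = out.begin();

  for (int w0 = 0; w0 < W; w0 += ws) {
    const int wn = std::min(ws, W - w0);
    Y.zeros((std::size_t)N * H * wn, cout);
    for (int c0 = 0; c0 < C; c0 += cb) {
      const int c1 = std::min(C, c0 + cb);
      const int kc = kh * kw * (c1 - c0);
      if ((int)cols.n_rows != (int)((std::size_t)N * H * wn) || (int)cols.n_cols != kc)
        cols.set_size((std::size_t)N * H * wn, kc);
      im2col_strip(x.begin(), N, C, H, W, kh, kw, dil, w0, wn, c0, c1, cols);
      Y += cols * Wm.rows((std::size_t)kh * kw * c0, (std::size_t)kh * kw * c1 - 1);
    }
    for (int o = 0; o < cout; ++o) {
      const double b = bias[o];
      const double* yc = Y.colptr(o);
      for (int wl = 0; wl < wn; ++wl) {
        for (int h = 0; h < H; ++h) {
          const double* s = yc + (std::size_t)N * (h + (std::size_t)H * wl);
          double* d = op + (std::size_t)N * (o + (std::size_t)cout * (h + (std::size_t)H * (w0 + wl)));
          for (int n = 0; n < N; ++n) d[n] = s[n] + b;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector wgt, NumericVector gy, int dil,
               bool need_gx) {
  int N, C, H, W;
  get_dims4(x, N, C, H, W);
  IntegerVector wd = wgt.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  const int K = kh * kw * cin;

  arma::mat Wm(const_cast<double*>(wgt.begin()), K, cout, false, true);
  arma::mat gW(K, cout, arma::fill::zeros);
  arma::rowvec gb(cout, arma::fill::zeros);

  NumericVector gx;
  double* gxp = nullptr;
  if (need_gx) {
    gx = NumericVector((std::size_t)N * C * H * W);
    gx.attr("dim") = IntegerVector::create(N, C, H, W);
    gxp = gx.begin();
  }

  int cb = std::max(1, (int)(49152.0 / ((double)N * H * kh * kw)));
  if (cb > cin) cb = cin;
  const int Kb = kh * kw * cb;
  const int ws = strip_width(N, H, std::max(Kb, cout), W);
  arma::mat cols((std::size_t)N * H * ws, Kb);
  arma::mat G((std::size_t)N * H * ws, cout);
  const double* gp = gy.begin();

  for (int w0 = 0; w0 < W; w0 += ws) {
    const int wn = std::min(ws, W - w0);
    if ((int)G.n_rows != (int)((std::size_t)N * H * wn))
      G.set_size((std::size_t)N * H * wn, cout);
    // gather gy strip into (N*H*wn) x cout
    for (int o = 0; o < cout; ++o) {
      double* gc = G.colptr(o);
      for (int wl = 0; wl < wn; ++wl) {
        for (int h = 0; h < H; ++h) {
          const double* s = gp + (std::size_t)N * (o + (std::size_t)cout * (h + (std::size_t)H * (w0 + wl)));
          double* d = gc + (std::size_t)N * (h + (std::size_t)H * wl);
          for (int n = 0; n < N; ++n) d[n] = s[n];
        }
      }
    }
    gb += arma::sum(G, 0);
    for (int c0 = 0; c0 < cin; c0 += cb) {
      const int c1 = std::min(cin, c0 + cb);
      const int kc = kh * kw * (c1 - c0);
      if ((int)cols.n_rows != (int)G.n_rows || (int)cols.n_cols != kc)
        cols.set_size(G.n_rows, kc);
      im2col_strip(x.begin(), N, C, H, W, kh, kw, dil, w0, wn, c0, c1, cols);
      gW.rows((std::size_t)kh * kw * c0, (std::size_t)kh * kw * c1 - 1) += cols.t() * G;
      if (need_gx) {
        arma::mat D = G * Wm.rows((std::size_t)kh * kw * c0, (std::size_t)kh * kw * c1 - 1).t();
        col2im_strip(D, N, C, H, W, kh, kw, dil, w0, wn, c0, c1, gxp);
      }
    }
  }

  NumericVector gWr(gW.begin(), gW.end());
  gWr.attr("dim") = wd;
  NumericVector gbr(gb.begin(), gb.end());
  if (!need_gx) {
    return List::create(_["gx"] = R_NilValue, _["gw"] = gWr, _["gb"] = gbr);
  }
  return List::create(_["gx"] = gx, _["gw"] = gWr, _["gb"] = gbr);
}
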