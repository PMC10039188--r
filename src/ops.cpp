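// Low-level tensor kernels for the valid-padding U-Net: 2-D valid convolution
// (forward and backward), 2x2 max pooling, and nearest-neighbour 2x upsampling.
// Tensors are (rows, cols, channels) cubes; convolution weights arrive as an
// R array with dim (k, k, in_channels, out_channels).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void weight_dims(const NumericVector& w, int& k, int& cin, int& cout) {
  IntegerVector d = w.attr("dim");
  if (d.size() != 4 || d[0] != d[1])
    stop("conv weights must have dim (k, k, in_channels, out_channels)");
  k = d[0];
  cin = d[2];
  cout = d[3];
}

// [[Rcpp::export(name = ".conv_valid_forward")]]
arma::cube conv_valid_forward(const arma::cube& x, const NumericVector& w,
                              const arma::vec& b) {
  int k, cin, cout;
  weight_dims(w, k, cin, cout);
  if ((int)x.n_slices != cin) stop("input channel mismatch");
  int ho = (int)x.n_rows - k + 1, wo = (int)x.n_cols - k + 1;
  if (ho < 1 || wo < 1) stop("input smaller than kernel");
  arma::cube out(ho, wo, cout);
  const double* wp = w.begin();
  for (int co = 0; co < cout; ++co) {
    arma::mat& o = out.slice(co);
    o.fill(b[co]);
    for (int ci = 0; ci < cin; ++ci) {
      const arma::mat& xs = x.slice(ci);
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki) {
          double wv = wp[ki + k * (kj + k * (ci + cin * co))];
          if (wv != 0.0)
            o += wv * xs.submat(ki, kj, ki + ho - 1, kj + wo - 1);
        }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv_valid_backward")]]
List conv_valid_backward(const arma::cube& x, const NumericVector& w,
                         const arma::cube& gout) {
  int k, cin, cout;
  weight_dims(w, k, cin, cout);
  int ho = (int)gout.n_rows, wo = (int)gout.n_cols;
  arma::cube gx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  arma::vec gb(cout);
  const double* wp = w.begin();
  double* gp = gw.begin();
  for (int co = 0; co < cout; ++co) {
    const arma::mat& go = gout.slice(co);
    gb[co] = arma::accu(go);
    for (int ci = 0; ci < cin; ++ci) {
      const arma::mat& xs = x.slice(ci);
      arma::mat& gxs = gx.slice(ci);
      for (int kj = 0; kj < k; ++kj)
        for (int ki = 0; ki < k; ++ki) {
          int off = ki + k * (kj + k * (ci + cin * co));
          gp[off] += arma::accu(go % xs.submat(ki, kj, ki + ho - 1, kj + wo - 1));
          double wv = wp[off];
          if (wv != 0.0)
            gxs.submat(ki, kj, ki + ho - 1, kj + wo - 1) += wv * go;
        }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling with stride 2; records the argmax (0..3, column-major within
// the window) so the backward pass can scatter gradients exactly.
// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(const arma::cube& x) {
  if (x.n_rows % 2 || x.n_cols % 2) stop("maxpool2 requires even spatial dims");
  int ho = x.n_rows / 2, wo = x.n_cols / 2, c = x.n_slices;
  arma::cube y(ho, wo, c);
  arma::ucube idx(ho, wo, c);
  for (int s = 0; s < c; ++s) {
    const arma::mat& xs = x.slice(s);
    for (int j = 0; j < wo; ++j)
      for (int i = 0; i < ho; ++i) {
        double v00 = xs(2 * i, 2 * j), v10 = xs(2 * i + 1, 2 * j);
        double v01 = xs(2 * i, 2 * j + 1), v11 = xs(2 * i + 1, 2 * j + 1);
        double m = v00;
        unsigned a = 0;
        if (v10 > m) { m = v10; a = 1; }
        if (v01 > m) { m = v01; a = 2; }
        if (v11 > m) { m = v11; a = 3; }
        y(i, j, s) = m;
        idx(i, j, s) = a;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
arma::cube maxpool2_backward(const arma::cube& gy, const arma::ucube& idx) {
  int ho = gy.n_rows, wo = gy.n_cols, c = gy.n_slices;
  arma::cube gx(2 * ho, 2 * wo, c, arma::fill::zeros);
  for (int s = 0; s < c; ++s)
    for (int j = 0; j < wo; ++j)
      for (int i = 0; i < ho; ++i) {
        unsigned a = idx(i, j, s);
        gx(2 * i + (a & 1u), 2 * j + (a >> 1), s) = gy(i, j, s);
      }
  return gx;
}

// [[Rcpp::export(name = ".upsample2_forward")]]
arma::cube upsample2_forward(const arma::cube& x) {
  int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  arma::cube y(2 * h, 2 * w, c);
  for (int s = 0; s < c; ++s) {
    const arma::mat& xs = x.slice(s);
    arma::mat& ys = y.slice(s);
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        double v = xs(i, j);
        ys(2 * i, 2 * j) = v;
        ys(2 * i + 1, 2 * j) = v;
        ys(2 * i, 2 * j + 1) = v;
        ys(2 * i + 1, 2 * j + 1) = v;
      }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2_backward")]]
arma::cube upsample2_backward(const arma::cube& gy) {
  if (gy.n_rows % 2 || gy.n_cols % 2) stop("upsample2 backward requires even dims");
  int h = gy.n_rows / 2, w = gy.n_cols / 2, c = gy.n_slices;
  arma::cube gx(h, w, c);
  for (int s = 0; s < c; ++s) {
    const arma::mat& gs = gy.slice(s);
    arma::mat& gxs = gx.slice(s);
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i)
        gxs(i, j) = gs(2 * i, 2 * j) + gs(2 * i + 1, 2 * j) +
                    gs(2 * i, 2 * j + 1) + gs(2 * i + 1, 2 * j + 1);
  }
  return gx;
}

// ---- fused batched layer kernels ---------------------------------------
// These operate on whole batches (R arrays with dim (H, W, C, N)) through
// zero-copy views, avoiding R-level slicing on full-resolution tensors.

static inline void dims4(const NumericVector& x, int d[4]) {
  IntegerVector dd = x.attr("dim");
  if (dd.size() != 4) stop("expected a 4-d (H, W, C, N) array");
  for (int i = 0; i < 4; ++i) d[i] = dd[i];
}

static inline arma::mat slice_view(const NumericVector& x, const int d[4],
                                   int c, int n) {
  return arma::mat(const_cast<double*>(x.begin()) +
                   (size_t)d[0] * d[1] * (c + (size_t)d[2] * n),
                   d[0], d[1], false, true);
}

static NumericVector alloc4(int h, int w, int c, int n) {
  NumericVector y((size_t)h * w * c * n);
  y.attr("dim") = IntegerVector::create(h, w, c, n);
  return y;
}

static NumericVector alloc4_noinit(int h, int w, int c, int n) {
  NumericVector y(no_init((size_t)h * w * c * n));
  y.attr("dim") = IntegerVector::create(h, w, c, n);
  return y;
}

// Direct valid convolution of one sample: single pass over the output with
// per-pixel accumulation (cache-local in the column-major layout).
static void conv_sample_forward(const double* x, int hx, int wx, int cin,
                                const double* w, int k, int cout,
                                const double* b, double* y, int ho, int wo) {
  for (int co = 0; co < cout; ++co) {
    double* yc = y + (size_t)ho * wo * co;
    for (int j = 0; j < wo; ++j) {
      double* ycol = yc + (size_t)ho * j;
      for (int i = 0; i < ho; ++i) ycol[i] = b[co];
      for (int ci = 0; ci < cin; ++ci) {
        const double* xc = x + (size_t)hx * wx * ci;
        const double* wk = w + (size_t)k * k * (ci + (size_t)cin * co);
        for (int kj = 0; kj < k; ++kj) {
          const double* xcol = xc + (size_t)hx * (j + kj);
          for (int ki = 0; ki < k; ++ki) {
            double wv = wk[ki + k * kj];
            if (wv == 0.0) continue;
            const double* xs = xcol + ki;
            for (int i = 0; i < ho; ++i) ycol[i] += wv * xs[i];
          }
        }
      }
    }
  }
}

// Backward of the direct convolution for one sample: accumulates the weight
// and bias gradients and scatters the input gradient in one pass.
static void conv_sample_backward(const double* x, int hx, int wx, int cin,
                                 const double* w, int k, int cout,
                                 const double* gz, int ho, int wo,
                                 double* gx, double* gw, double* gb) {
  for (int co = 0; co < cout; ++co) {
    const double* gc = gz + (size_t)ho * wo * co;
    double gbacc = 0;
    for (int j = 0; j < wo; ++j) {
      const double* gcol = gc + (size_t)ho * j;
      for (int i = 0; i < ho; ++i) gbacc += gcol[i];
      for (int ci = 0; ci < cin; ++ci) {
        const double* xc = x + (size_t)hx * wx * ci;
        double* gxc = gx + (size_t)hx * wx * ci;
        double* gwk = gw + (size_t)k * k * (ci + (size_t)cin * co);
        const double* wk = w + (size_t)k * k * (ci + (size_t)cin * co);
        for (int kj = 0; kj < k; ++kj) {
          const double* xcol = xc + (size_t)hx * (j + kj);
          double* gxcol = gxc + (size_t)hx * (j + kj);
          for (int ki = 0; ki < k; ++ki) {
            const double* xs = xcol + ki;
            double* gxs = gxcol + ki;
            double wv = wk[ki + k * kj];
            double gwacc = 0;
            for (int i = 0; i < ho; ++i) {
              double g = gcol[i];
              gwacc += g * xs[i];
              gxs[i] += wv * g;
            }
            gwk[ki + k * kj] += gwacc;
          }
        }
      }
    }
    gb[co] += gbacc;
  }
}

// Convolution + optional batch norm + optional ReLU over a whole batch.
// Returns the activation, the pre-activation cache needed by the backward
// pass (xhat for BN), and updated running statistics in training mode.
// [[Rcpp::export(name = ".unit_forward")]]
List unit_forward_cpp(const NumericVector& x, const NumericVector& w,
                      const arma::vec& b, bool bn, const arma::vec& gamma,
                      const arma::vec& beta, const arma::vec& run_mean,
                      const arma::vec& run_var, bool train, double momentum,
                      double eps, bool relu, bool want_cache) {
  int dx[4];
  dims4(x, dx);
  int k, cin, cout;
  weight_dims(w, k, cin, cout);
  if (dx[2] != cin) stop("input channel mismatch");
  int ho = dx[0] - k + 1, wo = dx[1] - k + 1, n = dx[3];
  if (ho < 1 || wo < 1) stop("input smaller than kernel");
  NumericVector y = alloc4_noinit(ho, wo, cout, n);
  int dy[4] = {ho, wo, cout, n};
  for (int i = 0; i < n; ++i)
    conv_sample_forward(x.begin() + (size_t)dx[0] * dx[1] * dx[2] * i,
                        dx[0], dx[1], cin, w.begin(), k, cout, b.memptr(),
                        y.begin() + (size_t)ho * wo * cout * i, ho, wo);

  List out;
  if (bn) {
    arma::vec mu(cout), va(cout), inv_sd(cout);
    double m = (double)ho * wo * n;
    if (train) {
      for (int c = 0; c < cout; ++c) {
        double s = 0, s2 = 0;
        for (int i = 0; i < n; ++i) {
          arma::mat ys = slice_view(y, dy, c, i);
          s += arma::accu(ys);
          s2 += arma::accu(arma::square(ys));
        }
        mu[c] = s / m;
        va[c] = s2 / m - mu[c] * mu[c];
        if (va[c] < 0) va[c] = 0;
      }
      out["run_mean"] = (1 - momentum) * run_mean + momentum * mu;
      out["run_var"] = (1 - momentum) * run_var + momentum * va;
    } else {
      mu = run_mean;
      va = run_var;
    }
    inv_sd = 1.0 / arma::sqrt(va + eps);
    NumericVector xhat;
    bool keep_xhat = want_cache && train;
    if (keep_xhat) xhat = alloc4(ho, wo, cout, n);
    for (int c = 0; c < cout; ++c)
      for (int i = 0; i < n; ++i) {
        arma::mat ys = slice_view(y, dy, c, i);
        ys = (ys - mu[c]) * inv_sd[c];
        if (keep_xhat) {
          arma::mat xh = slice_view(xhat, dy, c, i);
          xh = ys;
        }
        ys = ys * gamma[c] + beta[c];
        if (relu) ys.transform([](double v) { return v > 0 ? v : 0.0; });
      }
    if (keep_xhat) out["xhat"] = xhat;
    out["inv_sd"] = inv_sd;
  } else if (relu) {
    for (int c = 0; c < cout; ++c)
      for (int i = 0; i < n; ++i) {
        arma::mat ys = slice_view(y, dy, c, i);
        ys.transform([](double v) { return v > 0 ? v : 0.0; });
      }
  }
  out["y"] = y;
  return out;
}

// Backward through ReLU + batch norm + convolution for a whole batch.
// [[Rcpp::export(name = ".unit_backward")]]
List unit_backward_cpp(const NumericVector& x, const NumericVector& w,
                       const NumericVector& y, const NumericVector& gy,
                       bool bn, const arma::vec& gamma,
                       const NumericVector& xhat, const arma::vec& inv_sd,
                       bool relu) {
  int dx[4], dy[4];
  dims4(x, dx);
  dims4(gy, dy);
  int k, cin, cout;
  weight_dims(w, k, cin, cout);
  int ho = dy[0], wo = dy[1], n = dy[3];
  NumericVector gz = alloc4_noinit(ho, wo, cout, n);

  // gradient through ReLU (mask from the activation) into gz
  for (int c = 0; c < cout; ++c)
    for (int i = 0; i < n; ++i) {
      arma::mat gzs = slice_view(gz, dy, c, i);
      arma::mat gys = slice_view(gy, dy, c, i);
      if (relu) {
        arma::mat ys = slice_view(y, dy, c, i);
        gzs = gys % (ys > 0);
      } else {
        gzs = gys;
      }
    }

  arma::vec ggamma(cout, arma::fill::zeros), gbeta(cout, arma::fill::zeros);
  if (bn) {
    double m = (double)ho * wo * n;
    for (int c = 0; c < cout; ++c) {
      double s1 = 0, s2 = 0, sg = 0;
      for (int i = 0; i < n; ++i) {
        arma::mat gzs = slice_view(gz, dy, c, i);
        arma::mat xh = slice_view(xhat, dy, c, i);
        s1 += arma::accu(gzs);
        s2 += arma::accu(gzs % xh);
        sg += arma::accu(gzs);
      }
      ggamma[c] = s2;
      gbeta[c] = s1;
      double gxh_mean = gamma[c] * s1 / m;
      double gxhx_mean = gamma[c] * s2 / m;
      for (int i = 0; i < n; ++i) {
        arma::mat gzs = slice_view(gz, dy, c, i);
        arma::mat xh = slice_view(xhat, dy, c, i);
        gzs = inv_sd[c] * (gamma[c] * gzs - gxh_mean - xh * gxhx_mean);
      }
    }
  }

  NumericVector gx = alloc4(dx[0], dx[1], dx[2], dx[3]);
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  arma::vec gb(cout, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    conv_sample_backward(x.begin() + (size_t)dx[0] * dx[1] * dx[2] * i,
                         dx[0], dx[1], cin, w.begin(), k, cout,
                         gz.begin() + (size_t)ho * wo * cout * i, ho, wo,
                         gx.begin() + (size_t)dx[0] * dx[1] * dx[2] * i,
                         gw.begin(), gb.memptr());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb,
                      _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export(name = ".pool_forward_batch")]]
List pool_forward_batch_cpp(const NumericVector& x) {
  int d[4];
  dims4(x, d);
  if (d[0] % 2 || d[1] % 2) stop("maxpool2 requires even spatial dims");
  int ho = d[0] / 2, wo = d[1] / 2;
  NumericVector y = alloc4(ho, wo, d[2], d[3]);
  IntegerVector idx((size_t)ho * wo * d[2] * d[3]);
  idx.attr("dim") = IntegerVector::create(ho, wo, d[2], d[3]);
  int dy[4] = {ho, wo, d[2], d[3]};
  int* ip = idx.begin();
  for (int n = 0; n < d[3]; ++n)
    for (int c = 0; c < d[2]; ++c) {
      arma::mat xs = slice_view(x, d, c, n);
      arma::mat ys = slice_view(y, dy, c, n);
      size_t base = (size_t)ho * wo * (c + (size_t)d[2] * n);
      for (int j = 0; j < wo; ++j)
        for (int i = 0; i < ho; ++i) {
          double v00 = xs(2 * i, 2 * j), v10 = xs(2 * i + 1, 2 * j);
          double v01 = xs(2 * i, 2 * j + 1), v11 = xs(2 * i + 1, 2 * j + 1);
          double m = v00;
          int a = 0;
          if (v10 > m) { m = v10; a = 1; }
          if (v01 > m) { m = v01; a = 2; }
          if (v11 > m) { m = v11; a = 3; }
          ys(i, j) = m;
          ip[base + i + (size_t)ho * j] = a;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".pool_backward_batch")]]
NumericVector pool_backward_batch_cpp(const NumericVector& gy,
                                      const IntegerVector& idx) {
  int d[4];
  dims4(gy, d);
  NumericVector gx = alloc4(2 * d[0], 2 * d[1], d[2], d[3]);
  int dg[4] = {2 * d[0], 2 * d[1], d[2], d[3]};
  const int* ip = idx.begin();
  for (int n = 0; n < d[3]; ++n)
    for (int c = 0; c < d[2]; ++c) {
      arma::mat gys = slice_view(gy, d, c, n);
      arma::mat gxs = slice_view(gx, dg, c, n);
      size_t base = (size_t)d[0] * d[1] * (c + (size_t)d[2] * n);
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i) {
          int a = ip[base + i + (size_t)d[0] * j];
          gxs(2 * i + (a & 1), 2 * j + (a >> 1)) = gys(i, j);
        }
    }
  return gx;
}

// [[Rcpp::export(name = ".upsample_forward_batch")]]
NumericVector upsample_forward_batch_cpp(const NumericVector& x) {
  int d[4];
  dims4(x, d);
  NumericVector y = alloc4(2 * d[0], 2 * d[1], d[2], d[3]);
  int dy[4] = {2 * d[0], 2 * d[1], d[2], d[3]};
  for (int n = 0; n < d[3]; ++n)
    for (int c = 0; c < d[2]; ++c) {
      arma::mat xs = slice_view(x, d, c, n);
      arma::mat ys = slice_view(y, dy, c, n);
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i) {
          double v = xs(i, j);
          ys(2 * i, 2 * j) = v;
          ys(2 * i + 1, 2 * j) = v;
          ys(2 * i, 2 * j + 1) = v;
          ys(2 * i + 1, 2 * j + 1) = v;
        }
    }
  return y;
}

// [[Rcpp::export(name = ".upsample_backward_batch")]]
NumericVector upsample_backward_batch_cpp(const NumericVector& gy) {
  int d[4];
  dims4(gy, d);
  if (d[0] % 2 || d[1] % 2) stop("upsample2 backward requires even dims");
  NumericVector gx = alloc4(d[0] / 2, d[1] / 2, d[2], d[3]);
  int dg[4] = {d[0] / 2, d[1] / 2, d[2], d[3]};
  for (int n = 0; n < d[3]; ++n)
    for (int c = 0; c < d[2]; ++c) {
      arma::mat gys = slice_view(gy, d, c, n);
      arma::mat gxs = slice_view(gx, dg, c, n);
      for (int j = 0; j < dg[1]; ++j)
        for (int i = 0; i < dg[0]; ++i)
          gxs(i, j) = gys(2 * i, 2 * j) + gys(2 * i + 1, 2 * j) +
                      gys(2 * i, 2 * j + 1) + gys(2 * i + 1, 2 * j + 1);
    }
  return gx;
}
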