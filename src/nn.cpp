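// Dense layer primitives for the dual-branch U-Net: valid (unpadded)
// convolution via im2col + GEMM, 2x2 max pooling, and 2x2 stride-2
// transposed convolution, each with its backward pass.
//
// Tensors are R numeric arrays in column-major layout with dims
// (H, W, C, N): index h + H*(w + W*(c + C*n)). Weights for k x k
// convolutions have dims (k, k, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static NumericVector make4d(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector make4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static void get_dims4(const NumericVector &x, int d[4]) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

// im2col for one sample: M(k*k*Cin, Ho*Wo), row = kh + k*(kw + k*ci),
// col = ho + Ho*wo
static void im2col(const double *x, int H, int W, int Cin, int k,
                   arma::mat &M) {
  const int Ho = H - k + 1, Wo = W - k + 1;
  for (int ci = 0; ci < Cin; ++ci)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int row = kh + k * (kw + k * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          const double *src = x + (kh) + (size_t)H * ((wo + kw) + (size_t)W * ci);
          double *dst = M.memptr() + row + (size_t)M.n_rows * ((size_t)Ho * wo);
          for (int ho = 0; ho < Ho; ++ho)
            dst[(size_t)M.n_rows * ho] = src[ho];
        }
      }
}

static void col2im_add(const arma::mat &M, int H, int W, int Cin, int k,
                       double *dx) {
  const int Ho = H - k + 1, Wo = W - k + 1;
  for (int ci = 0; ci < Cin; ++ci)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int row = kh + k * (kw + k * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          double *dst = dx + (kh) + (size_t)H * ((wo + kw) + (size_t)W * ci);
          const double *src =
              M.memptr() + row + (size_t)M.n_rows * ((size_t)Ho * wo);
          for (int ho = 0; ho < Ho; ++ho)
            dst[ho] += src[(size_t)M.n_rows * ho];
        }
      }
}

static arma::mat weight_matrix(const NumericVector &w, int k, int Cin,
                               int Cout) {
  arma::mat Wm(Cout, k * k * Cin);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          Wm(co, kh + k * (kw + k * ci)) =
              w[kh + (size_t)k * (kw + (size_t)k * (ci + (size_t)Cin * co))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b) {
  int d[4]; get_dims4(x, d);
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("weight/input channel mismatch");
  const int Ho = H - k + 1, Wo = W - k + 1;
  if (Ho < 1 || Wo < 1) stop("input smaller than kernel");
  NumericVector y = make4d(Ho, Wo, Cout, N);
  arma::mat Wm = weight_matrix(w, k, Cin, Cout);
  arma::mat M(k * k * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, k, M);
    arma::mat Y = Wm * M;  // Cout x (Ho*Wo)
    double *yp = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (size_t o = 0; o < (size_t)Ho * Wo; ++o)
      for (int co = 0; co < Cout; ++co)
        yp[o + (size_t)Ho * Wo * co] = Y(co, o) + b[co];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy) {
  int d[4]; get_dims4(x, d);
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cout = wd[3];
  const int Ho = H - k + 1, Wo = W - k + 1;
  arma::mat Wm = weight_matrix(w, k, Cin, Cout);
  arma::mat dWm(Cout, k * k * Cin, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx = make4d(H, W, Cin, N);
  arma::mat M(k * k * Cin, (size_t)Ho * Wo);
  arma::mat dY(Cout, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, k, M);
    const double *dyp = dy.begin() + (size_t)Ho * Wo * Cout * n;
    for (size_t o = 0; o < (size_t)Ho * Wo; ++o)
      for (int co = 0; co < Cout; ++co)
        dY(co, o) = dyp[o + (size_t)Ho * Wo * co];
    dWm += dY * M.t();
    db += arma::sum(dY, 1);
    arma::mat dM = Wm.t() * dY;
    col2im_add(dM, H, W, Cin, k, dx.begin() + (size_t)H * W * Cin * n);
  }
  NumericVector dw = make4d(k, k, Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kw = 0; kw < k; ++kw)
        for (int kh = 0; kh < k; ++kh)
          dw[kh + (size_t)k * (kw + (size_t)k * (ci + (size_t)Cin * co))] =
              dWm(co, kh + k * (kw + k * ci));
  NumericVector dbv(Cout);
  for (int co = 0; co < Cout; ++co) dbv[co] = db(co);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = dbv);
}

// 2x2 max pooling, stride 2. Returns pooled array and the within-window
// argmax (0..3 as dh + 2*dw) needed by the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  int d[4]; get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("max pooling requires even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4d(Ho, Wo, C, N);
  IntegerVector idx = make4i(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double *yp = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      int *ip = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; int bk = 0;
          for (int dw2 = 0; dw2 < 2; ++dw2)
            for (int dh = 0; dh < 2; ++dh) {
              double v = xp[(2 * ho + dh) + (size_t)H * (2 * wo + dw2)];
              if (v > best) { best = v; bk = dh + 2 * dw2; }
            }
          yp[ho + (size_t)Ho * wo] = best;
          ip[ho + (size_t)Ho * wo] = bk;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector idx,
                               int H, int W) {
  int d[4]; get_dims4(dy, d);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx = make4d(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *dyp = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      const int *ip = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double *dxp = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          int k = ip[ho + (size_t)Ho * wo];
          int dh = k % 2, dw2 = k / 2;
          dxp[(2 * ho + dh) + (size_t)H * (2 * wo + dw2)] +=
              dyp[ho + (size_t)Ho * wo];
        }
    }
  return dx;
}

// 2x2 stride-2 transposed convolution ("up-convolution").
// y[2i+dh, 2j+dw, co] = b[co] + sum_ci x[i,j,ci] * w[dh,dw,ci,co]
// [[Rcpp::export]]
NumericVector upconv2_fwd_cpp(NumericVector x, NumericVector w,
                              NumericVector b) {
  int d[4]; get_dims4(x, d);
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  if (wd[0] != 2 || wd[1] != 2 || wd[2] != Cin)
    stop("upconv weight must be (2,2,Cin,Cout)");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = make4d(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double *yp = y.begin() + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yp[i] = b[co];
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xp = x.begin() + (size_t)H * W * (ci + (size_t)Cin * n);
        const double w00 = w[0 + 2 * (0 + 2 * (ci + (size_t)Cin * co))];
        const double w10 = w[1 + 2 * (0 + 2 * (ci + (size_t)Cin * co))];
        const double w01 = w[0 + 2 * (1 + 2 * (ci + (size_t)Cin * co))];
        const double w11 = w[1 + 2 * (1 + 2 * (ci + (size_t)Cin * co))];
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double v = xp[i + (size_t)H * j];
            double *yb = yp + 2 * i + (size_t)Ho * (2 * j);
            yb[0] += v * w00;
            yb[1] += v * w10;
            yb[(size_t)Ho] += v * w01;
            yb[(size_t)Ho + 1] += v * w11;
          }
      }
    }
  return y;
}

// [[Rcpp::export]]
List upconv2_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy) {
  int d[4]; get_dims4(x, d);
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx = make4d(H, W, Cin, N);
  NumericVector dw = make4d(2, 2, Cin, Cout);
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double *dyp =
          dy.begin() + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) db[co] += dyp[i];
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xp = x.begin() + (size_t)H * W * (ci + (size_t)Cin * n);
        double *dxp = dx.begin() + (size_t)H * W * (ci + (size_t)Cin * n);
        const size_t wb = (size_t)4 * (ci + (size_t)Cin * co);
        const double w00 = w[wb + 0], w10 = w[wb + 1];
        const double w01 = w[wb + 2], w11 = w[wb + 3];
        double g00 = 0, g10 = 0, g01 = 0, g11 = 0;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i) {
            const double v = xp[i + (size_t)H * j];
            const double *yb = dyp + 2 * i + (size_t)Ho * (2 * j);
            const double a = yb[0], bq = yb[1];
            const double cq = yb[(size_t)Ho], dq = yb[(size_t)Ho + 1];
            dxp[i + (size_t)H * j] += a * w00 + bq * w10 + cq * w01 + dq * w11;
            g00 += v * a; g10 += v * bq; g01 += v * cq; g11 += v * dq;
          }
        dw[wb + 0] += g00; dw[wb + 1] += g10;
        dw[wb + 2] += g01; dw[wb + 3] += g11;
      }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Per-channel mean and (biased) variance over space and batch.
// [[Rcpp::export]]
List bn_stats_cpp(NumericVector x) {
  int d[4]; get_dims4(x, d);
  const int C = d[2], N = d[3];
  const size_t hw = (size_t)d[0] * d[1];
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double *xp = x.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) { s += xp[i]; s2 += xp[i] * xp[i]; }
    }
    const double m = s / (hw * N);
    mean[c] = m;
    var[c] = s2 / (hw * N) - m * m;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// Normalize with given per-channel stats and scale/shift; returns the
// output and the normalized activations (needed by the backward pass).
// [[Rcpp::export]]
List bn_apply_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                  NumericVector mean, NumericVector var, double eps) {
  int d[4]; get_dims4(x, d);
  const int C = d[2], N = d[3];
  const size_t hw = (size_t)d[0] * d[1];
  NumericVector y = make4d(d[0], d[1], C, N), xn = make4d(d[0], d[1], C, N);
  for (int c = 0; c < C; ++c) {
    const double sd = std::sqrt(var[c] + eps);
    for (int n = 0; n < N; ++n) {
      const size_t off = hw * (c + (size_t)C * n);
      const double *xp = x.begin() + off;
      double *yp = y.begin() + off, *np = xn.begin() + off;
      for (size_t i = 0; i < hw; ++i) {
        const double z = (xp[i] - mean[c]) / sd;
        np[i] = z;
        yp[i] = gamma[c] * z + beta[c];
      }
    }
  }
  return List::create(_["y"] = y, _["xn"] = xn);
}

// Backward pass of batch normalization (training mode, batch statistics).
// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dy, NumericVector xn, NumericVector gamma,
                NumericVector sd) {
  int d[4]; get_dims4(dy, d);
  const int C = d[2], N = d[3];
  const size_t hw = (size_t)d[0] * d[1];
  const double m = (double)hw * N;
  NumericVector dgamma(C), dbeta(C);
  NumericVector dx = make4d(d[0], d[1], C, N);
  for (int c = 0; c < C; ++c) {
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = hw * (c + (size_t)C * n);
      const double *dp = dy.begin() + off, *np = xn.begin() + off;
      for (size_t i = 0; i < hw; ++i) { sg += dp[i] * np[i]; sb += dp[i]; }
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double t1 = sb / m, t2 = sg / m, f = gamma[c] / sd[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = hw * (c + (size_t)C * n);
      const double *dp = dy.begin() + off, *np = xn.begin() + off;
      double *xp = dx.begin() + off;
      for (size_t i = 0; i < hw; ++i)
        xp[i] = f * (dp[i] - t1 - np[i] * t2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Fused ReLU backward: dx = dy * (pre > 0)
// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector dy, NumericVector pre) {
  NumericVector dx = clone(dy);
  for (R_xlen_t i = 0; i < dx.size(); ++i)
    if (pre[i] <= 0) dx[i] = 0;
  return dx;
}
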