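// Layer primitives for the modified U-Net.
// Tensor convention: 4D R arrays dim (H, W, C, N), column-major, doubles.
// Convolutions are stride 1 with size-preserving zero padding (odd kernels).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static IntegerVector dims_of(const NumericVector& x, int need) {
  IntegerVector d = x.attr("dim");
  if (d.size() != need) stop("expected a %d-d array", need);
  return d;
}

// Build im2col matrix (H*W x k*k*C) for sample n of x.
static void im2col(const double* x, int H, int W, int C, int k, arma::mat& out) {
  const int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * dj + k * k * c;
        double* o = out.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - pad;
          if (jj < 0 || jj >= W) {
            for (int i = 0; i < H; ++i) o[i + (size_t)H * j] = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)H * jj;
          for (int i = 0; i < H; ++i) {
            const int ii = i + di - pad;
            o[i + (size_t)H * j] = (ii < 0 || ii >= H) ? 0.0 : xcol[ii];
          }
        }
      }
    }
  }
}

// Scatter-add the im2col-shaped gradient back onto the input grid.
static void col2im_add(const arma::mat& gcol, int H, int W, int C, int k, double* gx) {
  const int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * dj + k * k * c;
        const double* g = gcol.colptr(col);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - pad;
          if (jj < 0 || jj >= W) continue;
          double* gcol2 = gc + (size_t)H * jj;
          for (int i = 0; i < H; ++i) {
            const int ii = i + di - pad;
            if (ii >= 0 && ii < H) gcol2[ii] += g[i + (size_t)H * j];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims_of(x, 4), wd = dims_of(w, 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != C) stop("kernel dims inconsistent with input");
  if (k % 2 == 0) stop("odd kernels only");
  NumericVector y(NumericVector((size_t)H * W * Cout * N));
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat Xcol((size_t)H * W, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, Xcol);
    arma::mat Y(y.begin() + (size_t)n * H * W * Cout, (size_t)H * W, Cout, false, true);
    Y = Xcol * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = dims_of(x, 4), wd = dims_of(w, 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  NumericVector gx((size_t)H * W * C * N), gw(w.size()), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, Cout, false, true);
  arma::mat GW(gw.begin(), (size_t)k * k * C, Cout, false, true);
  arma::rowvec GB(gb.begin(), Cout, false, true);
  arma::mat Xcol((size_t)H * W, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, Xcol);
    arma::mat GY(const_cast<double*>(gy.begin()) + (size_t)n * H * W * Cout,
                 (size_t)H * W, Cout, false, true);
    GW += Xcol.t() * GY;
    GB += arma::sum(GY, 0);
    arma::mat Gcol = GY * Wm.t();
    col2im_add(Gcol, H, W, C, k, gx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List nn_maxpool_fwd(NumericVector x) {
  IntegerVector xd = dims_of(x, 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++o) {
          double best = -1e300; size_t bi = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const size_t p = base + (size_t)(2 * i + di) + (size_t)H * (2 * j + dj);
              if (x[p] > best) { best = x[p]; bi = p; }
            }
          y[o] = best; idx[o] = (int)bi;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t o = 0; o < gy.size(); ++o) gx[idx[o]] += gy[o];
  return gx;
}

// Transposed 2x2 stride-2 convolution: non-overlapping output blocks.
// [[Rcpp::export]]
NumericVector nn_upconv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims_of(x, 4), wd = dims_of(w, 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cout = wd[3];
  if (wd[0] != 2 || wd[1] != 2 || wd[2] != C) stop("upconv kernel must be 2x2xCinxCout");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double* yp = y.begin() + ((size_t)n * Cout + co) * Ho * Wo;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          double acc[4] = {b[co], b[co], b[co], b[co]};
          for (int ci = 0; ci < C; ++ci) {
            const double xv = x[((size_t)n * C + ci) * H * W + i + (size_t)H * j];
            const double* wp = w.begin() + 4 * ((size_t)ci + (size_t)C * co);
            acc[0] += xv * wp[0]; acc[1] += xv * wp[1];
            acc[2] += xv * wp[2]; acc[3] += xv * wp[3];
          }
          yp[(2 * i)     + (size_t)Ho * (2 * j)]     = acc[0];
          yp[(2 * i + 1) + (size_t)Ho * (2 * j)]     = acc[1];
          yp[(2 * i)     + (size_t)Ho * (2 * j + 1)] = acc[2];
          yp[(2 * i + 1) + (size_t)Ho * (2 * j + 1)] = acc[3];
        }
    }
  return y;
}

// [[Rcpp::export]]
List nn_upconv_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = dims_of(x, 4), wd = dims_of(w, 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cout = wd[3], Ho = 2 * H;
  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  gx.attr("dim") = xd; gw.attr("dim") = wd;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* gp = gy.begin() + ((size_t)n * Cout + co) * Ho * (2 * W);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double g[4] = {
            gp[(2 * i)     + (size_t)Ho * (2 * j)],
            gp[(2 * i + 1) + (size_t)Ho * (2 * j)],
            gp[(2 * i)     + (size_t)Ho * (2 * j + 1)],
            gp[(2 * i + 1) + (size_t)Ho * (2 * j + 1)]};
          gb[co] += g[0] + g[1] + g[2] + g[3];
          for (int ci = 0; ci < C; ++ci) {
            const size_t xi = ((size_t)n * C + ci) * H * W + i + (size_t)H * j;
            const double xv = x[xi];
            double* gwp = gw.begin() + 4 * ((size_t)ci + (size_t)C * co);
            const double* wp = w.begin() + 4 * ((size_t)ci + (size_t)C * co);
            double acc = 0.0;
            for (int q = 0; q < 4; ++q) { gwp[q] += xv * g[q]; acc += wp[q] * g[q]; }
            gx[xi] += acc;
          }
        }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Batch normalization over (H, W, N) per channel; population statistics.
// [[Rcpp::export]]
List nn_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta, double eps) {
  IntegerVector xd = dims_of(x, 4);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  NumericVector y(x.size()), mean(C), var(C);
  y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) { s += xp[i]; s2 += xp[i] * xp[i]; }
    }
    const double m = s / (HW * N);
    const double v = s2 / (HW * N) - m * m;
    mean[c] = m; var[c] = v < 0 ? 0 : v;
    const double sc = gamma[c] / std::sqrt(var[c] + eps);
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + ((size_t)n * C + c) * HW;
      double* yp = y.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) yp[i] = sc * (xp[i] - m) + beta[c];
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector nn_bn_infer(NumericVector x, NumericVector gamma, NumericVector beta,
                          NumericVector rmean, NumericVector rvar, double eps) {
  IntegerVector xd = dims_of(x, 4);
  const int C = xd[2], N = xd[3];
  const size_t HW = (size_t)xd[0] * xd[1];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double sc = gamma[c] / std::sqrt(rvar[c] + eps);
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + ((size_t)n * C + c) * HW;
      double* yp = y.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) yp[i] = sc * (xp[i] - rmean[c]) + beta[c];
    }
  }
  return y;
}

// [[Rcpp::export]]
List nn_bn_bwd(NumericVector x, NumericVector gamma, NumericVector mean,
               NumericVector var, NumericVector gy, double eps) {
  IntegerVector xd = dims_of(x, 4);
  const int C = xd[2], N = xd[3];
  const size_t HW = (size_t)xd[0] * xd[1];
  const double inv_n = 1.0 / (double)(HW * N);
  NumericVector gx(x.size()), ggamma(C), gbeta(C);
  gx.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double isd = 1.0 / std::sqrt(var[c] + eps);
    double sg = 0.0, sgx = 0.0, sgam = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + ((size_t)n * C + c) * HW;
      const double* gp = gy.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        const double xh = (xp[i] - mean[c]) * isd;
        sg += gp[i]; sgx += gp[i] * xh; sgam += gp[i] * xh;
      }
    }
    ggamma[c] = sgam; gbeta[c] = sg;
    const double mg = sg * inv_n, mgx = sgx * inv_n;
    const double sc = gamma[c] * isd;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + ((size_t)n * C + c) * HW;
      const double* gp = gy.begin() + ((size_t)n * C + c) * HW;
      double* op = gx.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        const double xh = (xp[i] - mean[c]) * isd;
        op[i] = sc * (gp[i] - mg - xh * mgx);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
NumericVector nn_relu(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector nn_relu_bwd(NumericVector g, NumericVector x) {
  NumericVector o(g.size());
  o.attr("dim") = g.attr("dim");
  for (R_xlen_t i = 0; i < g.size(); ++i) o[i] = x[i] > 0 ? g[i] : 0.0;
  return o;
}

// One fused ADAM update; returns fresh (non-aliased) tensors.
// [[Rcpp::export]]
List nn_adam(NumericVector p, NumericVector g, NumericVector m, NumericVector v,
             double lr, double b1, double b2, double eps, double c1, double c2) {
  R_xlen_t n = p.size();
  NumericVector p2(n), m2(n), v2(n);
  p2.attr("dim") = p.attr("dim");
  for (R_xlen_t i = 0; i < n; ++i) {
    m2[i] = b1 * m[i] + (1 - b1) * g[i];
    v2[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
    p2[i] = p[i] - lr * (m2[i] / c1) / (std::sqrt(v2[i] / c2) + eps);
  }
  return List::create(_["p"] = p2, _["m"] = m2, _["v"] = v2);
}
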