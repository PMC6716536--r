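#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tensors are plain R arrays in column-major order:
//   activations x : (H, W, C, N)
//   conv weights w: (k, k, Cin, Cout), k odd, stride 1, "same" zero padding.
// Convolution is realised as im2col + BLAS matrix products per sample; the
// column index j = ki + k*(kj + k*c) matches the native layout of w, so the
// weight tensor can be used as a (k*k*Cin) x Cout matrix without copying.


static NumericVector make4d(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static void im2col(const double* x, int H, int W, int C, int k,
                   arma::mat& col) {
  const int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int j = ki + k * (kj + k * c);
        double* out = col.colptr(j);
        std::fill(out, out + (size_t)H * W, 0.0);
        const int dh = ki - pad, dw = kj - pad;
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        for (int w = w0; w < w1; ++w) {
          const double* src = xc + (size_t)H * (w + dw) + (h0 + dh);
          std::copy(src, src + (h1 - h0), out + (size_t)H * w + h0);
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, int H, int W, int C, int k,
                       double* x) {
  const int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int j = ki + k * (kj + k * c);
        const double* in = col.colptr(j);
        const int dh = ki - pad, dw = kj - pad;
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        for (int w = w0; w < w1; ++w) {
          double* dst = xc + (size_t)H * (w + dw) + (h0 + dh);
          const double* src = in + (size_t)H * w + h0;
          for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".convForward")]]
NumericVector convForward(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch in convForward");
  NumericVector y = make4d(H, W, Cout, N);
  arma::mat Wm(w.begin(), k * k * Cin, Cout, false, true);
  arma::rowvec bv(b.begin(), Cout);
  arma::mat col(H * W, k * k * Cin);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, col);
    arma::mat ym(y.begin() + (size_t)H * W * Cout * n, H * W, Cout,
                 false, true);
    ym = col * Wm;
    ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".convBackward")]]
List convBackward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  NumericVector dx = make4d(H, W, C, N);
  NumericVector dw = make4d(k, k, Cin, Cout);
  NumericVector db(Cout);
  arma::mat Wm(w.begin(), k * k * Cin, Cout, false, true);
  arma::mat dWm(dw.begin(), k * k * Cin, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat col(H * W, k * k * Cin);
  for (int n = 0; n < N; ++n) {
    const size_t xo = (size_t)H * W * C * n, yo = (size_t)H * W * Cout * n;
    arma::mat dym(const_cast<double*>(dy.begin()) + yo, H * W, Cout,
                  false, true);
    im2col(x.begin() + xo, H, W, C, k, col);
    dWm += col.t() * dym;
    dbv += arma::sum(dym, 0).t();
    arma::mat dcol = dym * Wm.t();
    col2im_add(dcol, H, W, C, k, dx.begin() + xo);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; H and W must be even.
// [[Rcpp::export(name = ".maxPoolForward")]]
List maxPoolForward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4d(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // 1-based linear index into x of the argmax
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++o) {
          size_t best = base + (size_t)H * (2 * w) + 2 * h;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const size_t p = base + (size_t)H * (2 * w + dw) + 2 * h + dh;
              if (xp[p] > xp[best]) best = p;
            }
          yp[o] = xp[best];
          ip[o] = (int)best + 1;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxPoolBackward")]]
NumericVector maxPoolBackward(IntegerVector idx, NumericVector dy,
                              IntegerVector dims) {
  NumericVector dx = make4d(dims[0], dims[1], dims[2], dims[3]);
  double* dxp = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) dxp[idx[i] - 1] += dy[i];
  return dx;
}

// Per-channel batch-norm helpers for (H, W, C, N) activations: channel c
// occupies contiguous blocks of H*W values within each sample.

// [[Rcpp::export(name = ".bnStats")]]
List bnStats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t hw = (size_t)H * W;
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / (hw * N);
    mu[c] = m;
    var[c] = s2 / (hw * N) - m * m;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// y = (x - mu[c]) * invstd[c] * gamma[c] + beta[c]
// [[Rcpp::export(name = ".bnApply")]]
NumericVector bnApply(NumericVector x, NumericVector mu, NumericVector invstd,
                      NumericVector gamma, NumericVector beta) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t hw = (size_t)H * W;
  NumericVector y = make4d(H, W, C, N);
  for (int c = 0; c < C; ++c) {
    const double a = invstd[c] * gamma[c];
    const double b = beta[c] - mu[c] * a;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      double* q = y.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) q[i] = p[i] * a + b;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".bnBackward")]]
List bnBackward(NumericVector x, NumericVector dy, NumericVector mu,
                NumericVector invstd, NumericVector gamma) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t hw = (size_t)H * W;
  const double m = (double)hw * N;
  NumericVector dx = make4d(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + hw * (c + (size_t)C * n);
      const double* pd = dy.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) {
        s1 += pd[i];
        s2 += pd[i] * (px[i] - mu[c]) * invstd[c];
      }
    }
    dgamma[c] = s2; dbeta[c] = s1;
    const double a = gamma[c] * invstd[c];
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + hw * (c + (size_t)C * n);
      const double* pd = dy.begin() + hw * (c + (size_t)C * n);
      double* q = dx.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) {
        const double xhat = (px[i] - mu[c]) * invstd[c];
        q[i] = a * (pd[i] - s1 / m - xhat * s2 / m);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Rectifies x in place (callers only pass freshly allocated activations)
// and returns it; the rectified output doubles as the backward mask.
// [[Rcpp::export(name = ".reluInPlace")]]
NumericVector reluInPlace(NumericVector x) {
  double* p = x.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
  return x;
}

// [[Rcpp::export(name = ".reluBackward")]]
NumericVector reluBackward(NumericVector out, NumericVector dy) {
  NumericVector dx = clone(dy);
  const double* o = out.begin();
  double* d = dx.begin();
  const R_xlen_t n = dx.size();
  for (R_xlen_t i = 0; i < n; ++i) if (o[i] <= 0) d[i] = 0;
  return dx;
}
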