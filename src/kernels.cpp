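// Low-level numeric kernels for the breathing network.
// Layout conventions: signals/features are (time x channels) matrices;
// a conv1d weight is a (kernel*in_ch) x out_ch matrix whose rows are ordered
// kernel-tap-major (tap 0 channels, tap 1 channels, ...).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_len(int t_in, int k, int stride, int pad) {
  return (t_in + 2 * pad - k) / stride + 1;
}

static arma::mat im2col(const arma::mat &X, int k, int stride, int pad) {
  const int t_in = X.n_rows, cin = X.n_cols;
  const int t_out = conv_out_len(t_in, k, stride, pad);
  arma::mat Xcol(t_out, k * cin, arma::fill::zeros);
  // column-major friendly: each (tap, channel) pair fills one contiguous
  // output column from a strided read of one input column
  for (int kk = 0; kk < k; ++kk) {
    for (int c = 0; c < cin; ++c) {
      const double *src = X.colptr(c);
      double *dst = Xcol.colptr(kk * cin + c);
      for (int t = 0; t < t_out; ++t) {
        const int p = t * stride + kk - pad;
        if (p >= 0 && p < t_in) dst[t] = src[p];
      }
    }
  }
  return Xcol;
}

// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::mat &X, int k, int stride, int pad) {
  return im2col(X, k, stride, pad);
}

// Scatter-add of column gradients back onto the input time grid.
// [[Rcpp::export]]
arma::mat cpp_col2im(const arma::mat &gXcol, int t_in, int cin, int k,
                     int stride, int pad) {
  arma::mat gX(t_in, cin, arma::fill::zeros);
  const int t_out = gXcol.n_rows;
  for (int kk = 0; kk < k; ++kk) {
    for (int c = 0; c < cin; ++c) {
      const double *src = gXcol.colptr(kk * cin + c);
      double *dst = gX.colptr(c);
      for (int t = 0; t < t_out; ++t) {
        const int p = t * stride + kk - pad;
        if (p >= 0 && p < t_in) dst[p] += src[t];
      }
    }
  }
  return gX;
}

// [[Rcpp::export]]
arma::mat cpp_conv1d_fw(const arma::mat &X, const arma::mat &W,
                        const arma::rowvec &b, int k, int stride, int pad) {
  arma::mat Y;
  if (k == 1) {
    // pointwise convolution: plain (strided) matrix product
    if (stride == 1) {
      Y = X * W;
    } else {
      arma::uvec rows = arma::regspace<arma::uvec>(0, stride, X.n_rows - 1);
      Y = X.rows(rows) * W;
    }
  } else {
    Y = im2col(X, k, stride, pad) * W;
  }
  Y.each_row() += b;
  return Y;
}

// [[Rcpp::export]]
List cpp_conv1d_bw(const arma::mat &X, const arma::mat &W, const arma::mat &gY,
                   int k, int stride, int pad) {
  const int t_in = X.n_rows, cin = X.n_cols;
  if (k == 1) {
    arma::uvec rows = arma::regspace<arma::uvec>(0, stride, t_in - 1);
    arma::mat Xs = (stride == 1) ? X : arma::mat(X.rows(rows));
    arma::mat gW = Xs.t() * gY;
    arma::rowvec gb = arma::sum(gY, 0);
    arma::mat gXs = gY * W.t();
    arma::mat gX;
    if (stride == 1) {
      gX = gXs;
    } else {
      gX.zeros(t_in, cin);
      gX.rows(rows) = gXs;
    }
    return List::create(_["gX"] = gX, _["gW"] = gW, _["gb"] = gb);
  }
  arma::mat Xcol = im2col(X, k, stride, pad);
  arma::mat gW = Xcol.t() * gY;
  arma::rowvec gb = arma::sum(gY, 0);
  arma::mat gXcol = gY * W.t();
  arma::mat gX(t_in, cin, arma::fill::zeros);
  const int t_out = gY.n_rows;
  for (int kk = 0; kk < k; ++kk) {
    for (int c = 0; c < cin; ++c) {
      const double *src = gXcol.colptr(kk * cin + c);
      double *dst = gX.colptr(c);
      for (int t = 0; t < t_out; ++t) {
        const int p = t * stride + kk - pad;
        if (p >= 0 && p < t_in) dst[p] += src[t];
      }
    }
  }
  return List::create(_["gX"] = gX, _["gW"] = gW, _["gb"] = gb);
}

// Simple recurrent unit (light recurrence + highway skip).
// U = X %*% W holds the three projections [candidate | forget | reset].
// f_t = sigmoid(u2_t + bf); r_t = sigmoid(u3_t + br)
// c_t = f_t*c_{t-1} + (1-f_t)*u1_t;  h_t = r_t*tanh(c_t) + (1-r_t)*x_t
// [[Rcpp::export]]
List cpp_sru_fw(const arma::mat &X, const arma::mat &U,
                const arma::rowvec &bf, const arma::rowvec &br) {
  const int T = X.n_rows, h = X.n_cols;
  arma::mat H(T, h), C(T, h);
  std::vector<double> c(h, 0.0);
  for (int j = 0; j < h; ++j) {
    const double *u1 = U.colptr(j), *u2 = U.colptr(h + j), *u3 = U.colptr(2 * h + j);
    const double *x = X.colptr(j);
    double *hc = H.colptr(j), *cc = C.colptr(j);
    const double bfj = bf[j], brj = br[j];
    double cj = 0.0;
    for (int t = 0; t < T; ++t) {
      const double f = 1.0 / (1.0 + std::exp(-(u2[t] + bfj)));
      const double r = 1.0 / (1.0 + std::exp(-(u3[t] + brj)));
      cj = f * cj + (1.0 - f) * u1[t];
      cc[t] = cj;
      hc[t] = r * std::tanh(cj) + (1.0 - r) * x[t];
    }
    c[j] = cj;
  }
  return List::create(_["H"] = H, _["C"] = C);
}

// [[Rcpp::export]]
List cpp_sru_bw(const arma::mat &X, const arma::mat &U,
                const arma::rowvec &bf, const arma::rowvec &br,
                const arma::mat &C, const arma::mat &gH) {
  const int T = X.n_rows, h = X.n_cols;
  arma::mat gX(T, h), gU(T, 3 * h);
  arma::rowvec gbf(h, arma::fill::zeros), gbr(h, arma::fill::zeros);
  for (int j = 0; j < h; ++j) {
    const double *u1 = U.colptr(j), *u2 = U.colptr(h + j), *u3 = U.colptr(2 * h + j);
    const double *x = X.colptr(j), *cc = C.colptr(j), *gh = gH.colptr(j);
    double *gx = gX.colptr(j), *gu1 = gU.colptr(j), *gu2 = gU.colptr(h + j),
           *gu3 = gU.colptr(2 * h + j);
    const double bfj = bf[j], brj = br[j];
    double gc = 0.0, sbf = 0.0, sbr = 0.0;
    for (int t = T - 1; t >= 0; --t) {
      const double f = 1.0 / (1.0 + std::exp(-(u2[t] + bfj)));
      const double r = 1.0 / (1.0 + std::exp(-(u3[t] + brj)));
      const double tc = std::tanh(cc[t]);
      const double g = gh[t];
      const double gr = g * (tc - x[t]);
      gx[t] = g * (1.0 - r);
      gc += g * r * (1.0 - tc * tc);
      const double cprev = (t > 0) ? cc[t - 1] : 0.0;
      const double gf = gc * (cprev - u1[t]);
      gu1[t] = gc * (1.0 - f);
      const double v2 = gf * f * (1.0 - f);
      const double v3 = gr * r * (1.0 - r);
      gu2[t] = v2;
      gu3[t] = v3;
      sbf += v2;
      sbr += v3;
      gc *= f;
    }
    gbf[j] = sbf;
    gbr[j] = sbr;
  }
  return List::create(_["gX"] = gX, _["gU"] = gU, _["gbf"] = gbf, _["gbr"] = gbr);
}

// Fused per-channel time normalization with affine and optional ReLU.
// Single-pass column loops; Xhat is stashed for the backward pass.
// [[Rcpp::export]]
List cpp_tnorm_fw(const arma::mat &X, const arma::rowvec &gamma,
                  const arma::rowvec &beta, double eps, bool relu) {
  const int n = X.n_rows, cdim = X.n_cols;
  arma::mat Y(n, cdim), Xhat(n, cdim);
  arma::rowvec inv(cdim);
  for (int c = 0; c < cdim; ++c) {
    const double *x = X.colptr(c);
    double *y = Y.colptr(c), *xh = Xhat.colptr(c);
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) s += x[i];
    const double mu = s / n;
    for (int i = 0; i < n; ++i) { const double d = x[i] - mu; s2 += d * d; }
    const double iv = 1.0 / std::sqrt(s2 / n + eps);
    inv[c] = iv;
    const double ga = gamma[c], be = beta[c];
    for (int i = 0; i < n; ++i) {
      const double h = (x[i] - mu) * iv;
      xh[i] = h;
      double v = h * ga + be;
      y[i] = (relu && v < 0) ? 0.0 : v;
    }
  }
  return List::create(_["Y"] = Y, _["Xhat"] = Xhat, _["inv"] = inv);
}

// [[Rcpp::export]]
List cpp_tnorm_bw(const arma::mat &Xhat, const arma::rowvec &inv,
                  const arma::rowvec &gamma, const arma::mat &Y,
                  const arma::mat &G_in, bool relu) {
  const int n = Xhat.n_rows, cdim = Xhat.n_cols;
  arma::mat gX(n, cdim);
  arma::rowvec ggamma(cdim), gbeta(cdim);
  for (int c = 0; c < cdim; ++c) {
    const double *xh = Xhat.colptr(c), *y = Y.colptr(c), *g0 = G_in.colptr(c);
    double *gx = gX.colptr(c);
    const double ga = gamma[c], iv = inv[c];
    double sg = 0, sgx = 0;
    for (int i = 0; i < n; ++i) {
      const double g = (relu && y[i] <= 0) ? 0.0 : g0[i];
      gx[i] = g;                     // temporarily store masked grad
      sg += g;
      sgx += g * xh[i];
    }
    ggamma[c] = sgx;
    gbeta[c] = sg;
    const double m1 = ga * sg / n, m2 = ga * sgx / n;
    for (int i = 0; i < n; ++i) {
      gx[i] = (gx[i] * ga - m1 - xh[i] * m2) * iv;
    }
  }
  return List::create(_["gX"] = gX, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// Residual join fused with ReLU: Y = max(A + B, 0).
// [[Rcpp::export]]
arma::mat cpp_addrelu_fw(const arma::mat &A, const arma::mat &B) {
  arma::mat Y = A + B;
  Y.for_each([](arma::mat::elem_type &v) { if (v < 0) v = 0; });
  return Y;
}

// [[Rcpp::export]]
arma::mat cpp_addrelu_bw(const arma::mat &Y, const arma::mat &G) {
  arma::mat gA = G;
  const int nn = Y.n_elem;
  const double *y = Y.memptr();
  double *g = gA.memptr();
  for (int i = 0; i < nn; ++i) if (y[i] <= 0) g[i] = 0;
  return gA;
}

// Fused conv1d -> time-norm -> (optional) ReLU, with stashes for backward.
// [[Rcpp::export]]
List cpp_cnr_fw(const arma::mat &X, const arma::mat &W, const arma::rowvec &b,
                const arma::rowvec &gamma, const arma::rowvec &beta,
                int k, int stride, int pad, double eps, bool relu) {
  arma::mat Xcol;
  if (k == 1) {
    if (stride == 1) Xcol = X;
    else {
      arma::uvec rows = arma::regspace<arma::uvec>(0, stride, X.n_rows - 1);
      Xcol = X.rows(rows);
    }
  } else {
    Xcol = im2col(X, k, stride, pad);
  }
  arma::mat Z = Xcol * W;
  Z.each_row() += b;
  const int n = Z.n_rows, cdim = Z.n_cols;
  arma::mat Y(n, cdim);
  arma::rowvec inv(cdim), mu(cdim);
  for (int c = 0; c < cdim; ++c) {
    const double *z = Z.colptr(c);
    double *y = Y.colptr(c);
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) s += z[i];
    const double m = s / n;
    for (int i = 0; i < n; ++i) { const double d = z[i] - m; s2 += d * d; }
    const double iv = 1.0 / std::sqrt(s2 / n + eps);
    inv[c] = iv;
    mu[c] = m;
    const double ga = gamma[c], be = beta[c];
    for (int i = 0; i < n; ++i) {
      const double v = (z[i] - m) * iv * ga + be;
      y[i] = (relu && v < 0) ? 0.0 : v;
    }
  }
  return List::create(_["Y"] = Y, _["mu"] = mu, _["inv"] = inv);
}

// [[Rcpp::export]]
List cpp_cnr_bw(const arma::mat &X, const arma::rowvec &b,
                const arma::rowvec &mu, const arma::rowvec &inv,
                const arma::mat &W, const arma::rowvec &gamma,
                const arma::mat &Y, const arma::mat &G_in, int t_in, int cin,
                int k, int stride, int pad, bool relu) {
  // rebuild the patch matrix (cheaper than shipping it out of the fw call)
  arma::mat Xcol;
  if (k == 1) {
    if (stride == 1) Xcol = X;
    else {
      arma::uvec rows = arma::regspace<arma::uvec>(0, stride, X.n_rows - 1);
      Xcol = X.rows(rows);
    }
  } else {
    Xcol = im2col(X, k, stride, pad);
  }
  arma::mat Z = Xcol * W;
  Z.each_row() += b;
  const int n = Z.n_rows, cdim = Z.n_cols;
  arma::mat gZ(n, cdim);
  arma::rowvec ggamma(cdim), gbeta(cdim);
  for (int c = 0; c < cdim; ++c) {
    double *z = Z.colptr(c);  // overwritten with xhat below
    const double *y = Y.colptr(c), *g0 = G_in.colptr(c);
    double *gz = gZ.colptr(c);
    const double ga = gamma[c], iv = inv[c], m0 = mu[c];
    double sg = 0, sgx = 0;
    for (int i = 0; i < n; ++i) {
      const double xh = (z[i] - m0) * iv;
      z[i] = xh;
      const double g = (relu && y[i] <= 0) ? 0.0 : g0[i];
      gz[i] = g;
      sg += g;
      sgx += g * xh;
    }
    ggamma[c] = sgx;
    gbeta[c] = sg;
    const double m1 = ga * sg / n, m2 = ga * sgx / n;
    for (int i = 0; i < n; ++i) gz[i] = (gz[i] * ga - m1 - z[i] * m2) * iv;
  }
  arma::mat gW = Xcol.t() * gZ;
  arma::rowvec gb = arma::sum(gZ, 0);
  arma::mat gXcol = gZ * W.t();
  arma::mat gX;
  if (k == 1) {
    if (stride == 1) {
      gX = gXcol;
    } else {
      gX.zeros(t_in, cin);
      arma::uvec rows = arma::regspace<arma::uvec>(0, stride, t_in - 1);
      gX.rows(rows) = gXcol;
    }
  } else {
    gX.zeros(t_in, cin);
    for (int kk = 0; kk < k; ++kk) {
      for (int c = 0; c < cin; ++c) {
        const double *src = gXcol.colptr(kk * cin + c);
        double *dst = gX.colptr(c);
        for (int t = 0; t < n; ++t) {
          const int p = t * stride + kk - pad;
          if (p >= 0 && p < t_in) dst[p] += src[t];
        }
      }
    }
  }
  return List::create(_["gX"] = gX, _["gW"] = gW, _["gb"] = gb,
                      _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
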