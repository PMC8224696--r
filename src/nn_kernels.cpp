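// Hot numerical kernels for the 1-D network. Activations are column-major
// arrays of shape (channels, length, batch). Stride-1 convolutions avoid
// im2col entirely: the batch is laid out as one padded (C, Lp*B) slab and
// the convolution is k accumulated BLAS gemms, one per kernel tap, each
// reading a shifted column window of the slab. Columns that straddle two
// samples produce values outside every sample's valid output range and are
// simply not extracted. Strided convolutions (a minority of the compute)
// use a conventional im2col gather.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_len(int L, int k, int stride, int pad) {
  return (L + 2 * pad - k) / stride + 1;
}

// (C, L, B) -> padded slab (C, Lp*B), zero pad columns at both ends of
// every sample.
static arma::mat pad_slab(const double* x, int C, int L, int B, int pad) {
  const int Lp = L + 2 * pad;
  arma::mat xp(C, static_cast<size_t>(Lp) * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    std::memcpy(xp.colptr(static_cast<size_t>(b) * Lp + pad),
                x + static_cast<size_t>(b) * C * L,
                static_cast<size_t>(C) * L * sizeof(double));
  }
  return xp;
}

static arma::mat im2col(const double* x, int C, int L, int B, int k,
                        int stride, int pad) {
  const int Lout = out_len(L, k, stride, pad);
  arma::mat cols(C * k, static_cast<size_t>(Lout) * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* xb = x + static_cast<size_t>(b) * C * L;
    for (int l = 0; l < Lout; ++l) {
      double* dst = cols.colptr(static_cast<size_t>(b) * Lout + l);
      const int start = l * stride - pad;
      for (int tap = 0; tap < k; ++tap) {
        const int pos = start + tap;
        if (pos >= 0 && pos < L) {
          std::memcpy(dst + tap * C, xb + static_cast<size_t>(pos) * C,
                      C * sizeof(double));
        }
      }
    }
  }
  return cols;
}

// Single-precision padded slab: converts once while padding.
static arma::fmat pad_slab_f(const double* x, int C, int L, int B, int pad) {
  const int Lp = L + 2 * pad;
  arma::fmat xp(C, static_cast<size_t>(Lp) * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    float* dst = xp.colptr(static_cast<size_t>(b) * Lp + pad);
    const double* src = x + static_cast<size_t>(b) * C * L;
    const size_t nn = static_cast<size_t>(C) * L;
    for (size_t i = 0; i < nn; ++i) dst[i] = static_cast<float>(src[i]);
  }
  return xp;
}

// [[Rcpp::export]]
NumericVector conv1d_fw_cpp(NumericVector x, NumericMatrix W,
                            IntegerVector dims, int stride, int pad,
                            bool single = true) {
  const int C = dims[0], L = dims[1], B = dims[2];
  const int Cout = W.nrow();
  const int k = W.ncol() / C;
  const int Lout = out_len(L, k, stride, pad);
  arma::mat Wm(W.begin(), Cout, W.ncol(), false, true);
  NumericVector out(static_cast<size_t>(Cout) * Lout * B);
  if (stride == 1 && single) {
    const int Lp = L + 2 * pad;
    arma::fmat xp = pad_slab_f(x.begin(), C, L, B, pad);
    const size_t nall = xp.n_cols - (k - 1);
    arma::fmat cols(static_cast<size_t>(C) * k, nall);
    const float* slab = xp.memptr();
    for (size_t j = 0; j < nall; ++j) {
      std::memcpy(cols.colptr(j), slab + j * C,
                  static_cast<size_t>(C) * k * sizeof(float));
    }
    arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wm);
    arma::fmat yfull = Wf * cols;
    for (int b = 0; b < B; ++b) {
      double* dst = out.begin() + static_cast<size_t>(b) * Cout * Lout;
      const float* src = yfull.colptr(static_cast<size_t>(b) * Lp);
      const size_t nn = static_cast<size_t>(Cout) * Lout;
      for (size_t i = 0; i < nn; ++i) dst[i] = src[i];
    }
  } else if (stride == 1) {
    const int Lp = L + 2 * pad;
    arma::mat xp = pad_slab(x.begin(), C, L, B, pad);
    const size_t nall = xp.n_cols - (k - 1);
    // For stride 1 the im2col column j is the contiguous slab slice
    // starting at element j*C, so unrolling is one big memcpy per column.
    arma::mat cols(static_cast<size_t>(C) * k, nall);
    const double* slab = xp.memptr();
    for (size_t j = 0; j < nall; ++j) {
      std::memcpy(cols.colptr(j), slab + j * C,
                  static_cast<size_t>(C) * k * sizeof(double));
    }
    arma::mat yfull = Wm * cols;
    for (int b = 0; b < B; ++b) {
      std::memcpy(out.begin() + static_cast<size_t>(b) * Cout * Lout,
                  yfull.colptr(static_cast<size_t>(b) * Lp),
                  static_cast<size_t>(Cout) * Lout * sizeof(double));
    }
  } else {
    arma::mat cols = im2col(x.begin(), C, L, B, k, stride, pad);
    arma::mat y = Wm * cols;
    std::memcpy(out.begin(), y.memptr(), y.n_elem * sizeof(double));
  }
  out.attr("dim") = IntegerVector::create(Cout, Lout, B);
  return out;
}

// [[Rcpp::export]]
List conv1d_bw_cpp(NumericVector dy, NumericVector x, NumericMatrix W,
                   IntegerVector dims, int stride, int pad,
                   bool single = true) {
  const int C = dims[0], L = dims[1], B = dims[2];
  const int Cout = W.nrow();
  const int k = W.ncol() / C;
  const int Lout = out_len(L, k, stride, pad);
  arma::mat Wm(W.begin(), Cout, W.ncol(), false, true);
  NumericVector dx(static_cast<size_t>(C) * L * B);
  NumericMatrix dW(Cout, W.ncol());
  arma::mat dWm(dW.begin(), Cout, W.ncol(), false, true);
  if (stride == 1 && single) {
    const int Lp = L + 2 * pad;
    arma::fmat xp = pad_slab_f(x.begin(), C, L, B, pad);
    const size_t ncols = xp.n_cols;
    const size_t nall = ncols - (k - 1);
    arma::fmat cols(static_cast<size_t>(C) * k, nall);
    const float* slab = xp.memptr();
    for (size_t j = 0; j < nall; ++j) {
      std::memcpy(cols.colptr(j), slab + j * C,
                  static_cast<size_t>(C) * k * sizeof(float));
    }
    arma::fmat dyfull(Cout, nall, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      float* dst = dyfull.colptr(static_cast<size_t>(b) * Lp);
      const double* src = dy.begin() + static_cast<size_t>(b) * Cout * Lout;
      const size_t nn = static_cast<size_t>(Cout) * Lout;
      for (size_t i = 0; i < nn; ++i) dst[i] = static_cast<float>(src[i]);
    }
    arma::fmat Wf = arma::conv_to<arma::fmat>::from(Wm);
    arma::fmat dWf = dyfull * cols.t();
    for (size_t i = 0; i < dWf.n_elem; ++i) dWm.memptr()[i] = dWf.memptr()[i];
    arma::fmat dcols = Wf.t() * dyfull;
    arma::fvec dslab(static_cast<size_t>(C) * ncols, arma::fill::zeros);
    float* ds = dslab.memptr();
    const float* dc = dcols.memptr();
    const size_t ck = static_cast<size_t>(C) * k;
    for (size_t j = 0; j < nall; ++j) {
      float* d = ds + j * C;
      const float* s = dc + j * ck;
      for (size_t t = 0; t < ck; ++t) d[t] += s[t];
    }
    for (int b = 0; b < B; ++b) {
      double* dst = dx.begin() + static_cast<size_t>(b) * C * L;
      const float* src = ds + (static_cast<size_t>(b) * Lp + pad) * C;
      const size_t nn = static_cast<size_t>(C) * L;
      for (size_t i = 0; i < nn; ++i) dst[i] = src[i];
    }
  } else if (stride == 1) {
    const int Lp = L + 2 * pad;
    arma::mat xp = pad_slab(x.begin(), C, L, B, pad);
    const size_t ncols = xp.n_cols;
    const size_t nall = ncols - (k - 1);
    arma::mat cols(static_cast<size_t>(C) * k, nall);
    const double* slab = xp.memptr();
    for (size_t j = 0; j < nall; ++j) {
      std::memcpy(cols.colptr(j), slab + j * C,
                  static_cast<size_t>(C) * k * sizeof(double));
    }
    // scatter dy into the padded slab layout; straddling columns stay zero
    arma::mat dyfull(Cout, nall, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      std::memcpy(dyfull.colptr(static_cast<size_t>(b) * Lp),
                  dy.begin() + static_cast<size_t>(b) * Cout * Lout,
                  static_cast<size_t>(Cout) * Lout * sizeof(double));
    }
    dWm = dyfull * cols.t();
    arma::mat dcols = Wm.t() * dyfull;   // (C*k) x nall
    // col2im: add column j of dcols onto the slab slice starting at j*C
    arma::vec dslab(static_cast<size_t>(C) * ncols, arma::fill::zeros);
    double* ds = dslab.memptr();
    const double* dc = dcols.memptr();
    const size_t ck = static_cast<size_t>(C) * k;
    for (size_t j = 0; j < nall; ++j) {
      double* d = ds + j * C;
      const double* s = dc + j * ck;
      for (size_t t = 0; t < ck; ++t) d[t] += s[t];
    }
    for (int b = 0; b < B; ++b) {
      std::memcpy(dx.begin() + static_cast<size_t>(b) * C * L,
                  ds + (static_cast<size_t>(b) * Lp + pad) * C,
                  static_cast<size_t>(C) * L * sizeof(double));
    }
  } else {
    arma::mat cols = im2col(x.begin(), C, L, B, k, stride, pad);
    arma::mat dym(dy.begin(), Cout, static_cast<size_t>(Lout) * B, false, true);
    dWm = dym * cols.t();
    arma::mat dcols = Wm.t() * dym;
    double* dxp = dx.begin();
    for (int b = 0; b < B; ++b) {
      double* dxb = dxp + static_cast<size_t>(b) * C * L;
      for (int l = 0; l < Lout; ++l) {
        const double* src = dcols.colptr(static_cast<size_t>(b) * Lout + l);
        const int start = l * stride - pad;
        for (int tap = 0; tap < k; ++tap) {
          const int pos = start + tap;
          if (pos >= 0 && pos < L) {
            double* d = dxb + static_cast<size_t>(pos) * C;
            const double* s = src + tap * C;
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, L, B);
  return List::create(_["dx"] = dx, _["dW"] = dW);
}

// [[Rcpp::export]]
List maxpool_fw_cpp(NumericVector x, IntegerVector dims, int k, int stride,
                    int pad) {
  const int C = dims[0], L = dims[1], B = dims[2];
  const int Lout = out_len(L, k, stride, pad);
  NumericVector y(static_cast<size_t>(C) * Lout * B);
  IntegerVector amax(static_cast<size_t>(C) * Lout * B);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = amax.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = xp + static_cast<size_t>(b) * C * L;
    for (int l = 0; l < Lout; ++l) {
      double* yd = yp + (static_cast<size_t>(b) * Lout + l) * C;
      int* ad = ap + (static_cast<size_t>(b) * Lout + l) * C;
      const int start = l * stride - pad;
      for (int c = 0; c < C; ++c) {
        double best = -HUGE_VAL;
        int besttap = -1;
        for (int tap = 0; tap < k; ++tap) {
          const int pos = start + tap;
          if (pos < 0 || pos >= L) continue;
          const double v = xb[static_cast<size_t>(pos) * C + c];
          if (v > best) { best = v; besttap = tap; }
        }
        yd[c] = best;
        ad[c] = besttap;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, Lout, B);
  return List::create(_["y"] = y, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool_bw_cpp(NumericVector dy, IntegerVector amax,
                             IntegerVector dims, int k, int stride, int pad) {
  const int C = dims[0], L = dims[1], B = dims[2];
  const int Lout = out_len(L, k, stride, pad);
  NumericVector dx(static_cast<size_t>(C) * L * B);
  const double* dyp = dy.begin();
  const int* ap = amax.begin();
  double* dxp = dx.begin();
  for (int b = 0; b < B; ++b) {
    double* dxb = dxp + static_cast<size_t>(b) * C * L;
    for (int l = 0; l < Lout; ++l) {
      const double* dyd = dyp + (static_cast<size_t>(b) * Lout + l) * C;
      const int* ad = ap + (static_cast<size_t>(b) * Lout + l) * C;
      const int start = l * stride - pad;
      for (int c = 0; c < C; ++c) {
        if (ad[c] >= 0) {
          dxb[static_cast<size_t>(start + ad[c]) * C + c] += dyd[c];
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, L, B);
  return dx;
}

// Batch norm forward over (C, L*B) with per-channel statistics, fused
// normalize-scale-shift (single pass after the moment pass).
// [[Rcpp::export]]
List bn_fw_cpp(NumericVector x, IntegerVector dims, NumericVector gamma,
               NumericVector beta, NumericVector theta, bool training,
               NumericVector run_mean, NumericVector run_var,
               double momentum, double eps) {
  const int C = dims[0];
  const size_t n = static_cast<size_t>(dims[1]) * dims[2];
  const double* xp = x.begin();
  std::vector<double> mu(C), v(C);
  if (training) {
    std::vector<double> s1(C, 0.0), s2(C, 0.0);
    for (size_t j = 0; j < n; ++j) {
      const double* col = xp + j * C;
      for (int c = 0; c < C; ++c) {
        s1[c] += col[c];
        s2[c] += col[c] * col[c];
      }
    }
    for (int c = 0; c < C; ++c) {
      mu[c] = s1[c] / n;
      v[c] = std::max(s2[c] / n - mu[c] * mu[c], 0.0);
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = run_mean[c];
      v[c] = run_var[c];
    }
  }
  std::vector<double> invstd(C), a(C), b(C);
  for (int c = 0; c < C; ++c) {
    invstd[c] = 1.0 / std::sqrt(v[c] + eps);
    a[c] = gamma[c] * invstd[c];
    b[c] = beta[c] - theta[c] - a[c] * mu[c];
  }
  NumericVector y(x.size());
  double* yp = y.begin();
  NumericVector xhat;
  if (training) {
    xhat = NumericVector(x.size());
    double* xh = xhat.begin();
    for (size_t j = 0; j < n; ++j) {
      const double* col = xp + j * C;
      double* xhc = xh + j * C;
      double* yc = yp + j * C;
      for (int c = 0; c < C; ++c) {
        xhc[c] = (col[c] - mu[c]) * invstd[c];
        yc[c] = a[c] * col[c] + b[c];
      }
    }
    xhat.attr("dim") = dims;
  } else {
    for (size_t j = 0; j < n; ++j) {
      const double* col = xp + j * C;
      double* yc = yp + j * C;
      for (int c = 0; c < C; ++c) yc[c] = a[c] * col[c] + b[c];
    }
  }
  y.attr("dim") = dims;
  List out = List::create(_["y"] = y, _["xhat"] = xhat,
                          _["invstd"] = NumericVector(invstd.begin(), invstd.end()));
  if (training) {
    NumericVector nm(C), nv(C);
    for (int c = 0; c < C; ++c) {
      nm[c] = (1 - momentum) * run_mean[c] + momentum * mu[c];
      nv[c] = (1 - momentum) * run_var[c] + momentum * v[c];
    }
    out["run_mean"] = nm;
    out["run_var"] = nv;
  }
  return out;
}

// [[Rcpp::export]]
List bn_bw_cpp(NumericVector dy, NumericVector xhat, NumericVector invstd,
               NumericVector gamma, IntegerVector dims) {
  const int C = dims[0];
  const size_t n = static_cast<size_t>(dims[1]) * dims[2];
  const double* dyp = dy.begin();
  const double* xh = xhat.begin();
  NumericVector dgamma(C), dbeta(C);
  for (size_t j = 0; j < n; ++j) {
    const double* dyc = dyp + j * C;
    const double* xhc = xh + j * C;
    for (int c = 0; c < C; ++c) {
      dgamma[c] += dyc[c] * xhc[c];
      dbeta[c] += dyc[c];
    }
  }
  std::vector<double> mdy(C), mdyxh(C), gi(C);
  for (int c = 0; c < C; ++c) {
    mdy[c] = dbeta[c] / n;
    mdyxh[c] = dgamma[c] / n;
    gi[c] = gamma[c] * invstd[c];
  }
  NumericVector dx(dy.size());
  double* dxp = dx.begin();
  for (size_t j = 0; j < n; ++j) {
    const double* dyc = dyp + j * C;
    const double* xhc = xh + j * C;
    double* dxc = dxp + j * C;
    for (int c = 0; c < C; ++c) {
      dxc[c] = gi[c] * (dyc[c] - mdy[c] - xhc[c] * mdyxh[c]);
    }
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Fused activation kernels (in place on a fresh copy).
// [[Rcpp::export]]
NumericVector relu_fw_cpp(NumericVector x) {
  NumericVector y = clone(x);
  double* p = y.begin();
  const size_t n = y.size();
  for (size_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bw_cpp(NumericVector dy, NumericVector ref) {
  NumericVector dx = clone(dy);
  double* p = dx.begin();
  const double* r = ref.begin();
  const size_t n = dx.size();
  for (size_t i = 0; i < n; ++i) if (r[i] <= 0) p[i] = 0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}
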