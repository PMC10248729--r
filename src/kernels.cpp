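// Numerical kernels for the network and image ops.
// Tensor layout everywhere: column-major R arrays dim = (H, W, C, N);
// convolution weights dim = (kh, kw, Cin, Cout). Convolutions are
// stride-1, zero-padded to preserve the spatial size ("same"), with an
// optional dilation rate applied to the kernel taps.
#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector make4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Convolution without unfolding: for every kernel tap (ki, kj) the
// shifted input plane is multiplied into the output with one accumulating
// BLAS GEMM (the (HW x Cin) sample matrix has leading dimension HW, and a
// row shift of dh + H*dw addresses the tap offset). Rows whose shifted
// pixel wraps across a column boundary (the zero-padding band) receive a
// wrong contribution from the GEMM; a scalar fix-up pass subtracts it.
// This keeps memory traffic at the size of the feature maps themselves
// instead of the k^2-fold im2col expansion.

static void dgemm_raw(const char* ta, const char* tb, int M, int N, int K,
                      double alpha, const double* A, int lda,
                      const double* B, int ldb,
                      double beta, double* C, int ldc) {
  F77_CALL(dgemm)(ta, tb, &M, &N, &K, &alpha, const_cast<double*>(A), &lda,
                  const_cast<double*>(B), &ldb, &beta, C, &ldc FCONE FCONE);
}

struct TapGeom {
  int off;        // row offset dh + H*dw into the (HW x C) sample matrix
  int A2, B2;     // GEMM row range [A2, B2)
  int dh;         // row shift (for the wrap fix-up band)
  int wlo, whi;   // valid column range
};

static TapGeom tap_geom(int H, int W, int ki, int kj, int kh, int kw, int dil) {
  const int ph = dil * (kh - 1) / 2, pw = dil * (kw - 1) / 2;
  const int dh = ki * dil - ph, dw = kj * dil - pw;
  TapGeom t;
  t.dh = dh;
  t.off = dh + H * dw;
  t.wlo = std::max(0, -dw);
  t.whi = W - 1 - std::max(0, dw);
  const int A = H * std::max(0, -dw), B = H * (W - std::max(0, dw));
  t.A2 = A + std::max(0, -dh);
  t.B2 = B - std::max(0, dh);
  return t;
}

// Iterate the wrap band of a tap: pixels p in [A2, B2) whose row index
// h = p mod H falls outside the valid shifted range.
template <typename F>
static void for_wrap_rows(const TapGeom& t, int H, F fn) {
  if (t.dh == 0) return;
  const int h0 = t.dh < 0 ? 0 : H - t.dh;
  const int h1 = t.dh < 0 ? -t.dh : H;
  for (int w = t.wlo; w <= t.whi; ++w) {
    const int base = H * w;
    for (int h = h0; h < h1; ++h) {
      const int p = base + h;
      if (p >= t.A2 && p < t.B2) fn(p);
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector wts,
                                 NumericVector bias, int dil) {
  IntegerVector xd = x.attr("dim"), wd = wts.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: weight input channels (%d) != input channels (%d)", (int)wd[2], C);
  const int HW = H * W, ntap = kh * kw;
  NumericVector out = make4(H, W, Cout, N);
  // contiguous (Cin x Cout) weight slice per tap
  std::vector<double> wtap((size_t)ntap * C * Cout);
  for (int kj = 0; kj < kw; ++kj)
    for (int ki = 0; ki < kh; ++ki) {
      double* wt = wtap.data() + (size_t)(ki + kh * kj) * C * Cout;
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < C; ++ci)
          wt[ci + (size_t)C * co] =
            wts[ki + (size_t)kh * (kj + (size_t)kw * (ci + (size_t)C * co))];
    }
  std::vector<TapGeom> taps(ntap);
  for (int kj = 0; kj < kw; ++kj)
    for (int ki = 0; ki < kh; ++ki)
      taps[ki + kh * kj] = tap_geom(H, W, ki, kj, kh, kw, dil);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)HW * C * n;
    double* on = out.begin() + (size_t)HW * Cout * n;
    for (int tI = 0; tI < ntap; ++tI) {
      const TapGeom& t = taps[tI];
      if (t.B2 <= t.A2) continue;
      const double* wt = wtap.data() + (size_t)tI * C * Cout;
      dgemm_raw("N", "N", t.B2 - t.A2, Cout, C, 1.0,
                xn + t.A2 + t.off, HW, wt, C, 1.0, on + t.A2, HW);
      for_wrap_rows(t, H, [&](int p) {
        for (int co = 0; co < Cout; ++co) {
          double s = 0;
          for (int ci = 0; ci < C; ++ci)
            s += xn[p + t.off + (size_t)HW * ci] * wt[ci + (size_t)C * co];
          on[p + (size_t)HW * co] -= s;
        }
      });
    }
    for (int co = 0; co < Cout; ++co) {
      double* oc = on + (size_t)HW * co;
      const double b = bias[co];
      for (int p = 0; p < HW; ++p) oc[p] += b;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector wts,
                         NumericVector gout, int dil) {
  IntegerVector xd = x.attr("dim"), wd = wts.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int HW = H * W, ntap = kh * kw;
  NumericVector gx = make4(H, W, C, N);
  NumericVector gw = make4(kh, kw, C, Cout);
  NumericVector gb(Cout);
  std::vector<double> wtap((size_t)ntap * C * Cout);
  std::vector<double> gwtap((size_t)ntap * C * Cout, 0.0);
  for (int kj = 0; kj < kw; ++kj)
    for (int ki = 0; ki < kh; ++ki) {
      double* wt = wtap.data() + (size_t)(ki + kh * kj) * C * Cout;
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < C; ++ci)
          wt[ci + (size_t)C * co] =
            wts[ki + (size_t)kh * (kj + (size_t)kw * (ci + (size_t)C * co))];
    }
  std::vector<TapGeom> taps(ntap);
  for (int kj = 0; kj < kw; ++kj)
    for (int ki = 0; ki < kh; ++ki)
      taps[ki + kh * kj] = tap_geom(H, W, ki, kj, kh, kw, dil);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)HW * C * n;
    const double* gn = gout.begin() + (size_t)HW * Cout * n;
    double* gxn = gx.begin() + (size_t)HW * C * n;
    for (int co = 0; co < Cout; ++co) {
      const double* gc = gn + (size_t)HW * co;
      double s = 0;
      for (int p = 0; p < HW; ++p) s += gc[p];
      gb[co] += s;
    }
    for (int tI = 0; tI < ntap; ++tI) {
      const TapGeom& t = taps[tI];
      if (t.B2 <= t.A2) continue;
      const double* wt = wtap.data() + (size_t)tI * C * Cout;
      double* gwt = gwtap.data() + (size_t)tI * C * Cout;
      const int nr = t.B2 - t.A2;
      // gx[p + off, ci] += gout[p, co] * W[ci, co]
      dgemm_raw("N", "T", nr, C, Cout, 1.0,
                gn + t.A2, HW, wt, C, 1.0, gxn + t.A2 + t.off, HW);
      // gW[ci, co] += x[p + off, ci] * gout[p, co]
      dgemm_raw("T", "N", C, Cout, nr, 1.0,
                xn + t.A2 + t.off, HW, gn + t.A2, HW, 1.0, gwt, C);
      for_wrap_rows(t, H, [&](int p) {
        for (int ci = 0; ci < C; ++ci) {
          double s = 0;
          for (int co = 0; co < Cout; ++co)
            s += gn[p + (size_t)HW * co] * wt[ci + (size_t)C * co];
          gxn[p + t.off + (size_t)HW * ci] -= s;
        }
        for (int co = 0; co < Cout; ++co) {
          const double g = gn[p + (size_t)HW * co];
          for (int ci = 0; ci < C; ++ci)
            gwt[ci + (size_t)C * co] -= xn[p + t.off + (size_t)HW * ci] * g;
        }
      });
    }
  }
  for (int kj = 0; kj < kw; ++kj)
    for (int ki = 0; ki < kh; ++ki) {
      const double* gwt = gwtap.data() + (size_t)(ki + kh * kj) * C * Cout;
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < C; ++ci)
          gw[ki + (size_t)kh * (kj + (size_t)kw * (ci + (size_t)C * co))] =
            gwt[ci + (size_t)C * co];
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_relu_forward(NumericVector x) {
  NumericVector out = clone(x);
  double* p = out.begin();
  for (R_xlen_t i = 0; i < out.size(); ++i) if (p[i] < 0) p[i] = 0;
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector out, NumericVector g) {
  NumericVector gx(g.size());
  for (R_xlen_t i = 0; i < g.size(); ++i) gx[i] = out[i] > 0 ? g[i] : 0.0;
  gx.attr("dim") = g.attr("dim");
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_sigmoid_backward(NumericVector s, NumericVector g) {
  NumericVector gx(g.size());
  for (R_xlen_t i = 0; i < g.size(); ++i) gx[i] = g[i] * s[i] * (1.0 - s[i]);
  gx.attr("dim") = g.attr("dim");
  return gx;
}

// Channel concatenation of 4D arrays sharing H, W, N.
// [[Rcpp::export]]
NumericVector cpp_concat_channels(List xs) {
  const int K = xs.size();
  std::vector<NumericVector> v(K);
  int Ctot = 0, H = 0, W = 0, N = 0;
  std::vector<int> chans(K);
  for (int k = 0; k < K; ++k) {
    v[k] = as<NumericVector>(xs[k]);
    IntegerVector d = v[k].attr("dim");
    if (k == 0) { H = d[0]; W = d[1]; N = d[3]; }
    chans[k] = d[2];
    Ctot += d[2];
  }
  NumericVector out = make4(H, W, Ctot, N);
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    double* dst = out.begin() + HW * Ctot * n;
    for (int k = 0; k < K; ++k) {
      const double* src = v[k].begin() + HW * chans[k] * n;
      std::copy(src, src + HW * chans[k], dst);
      dst += HW * chans[k];
    }
  }
  return out;
}

// Slice channels [from, from+len) out of a 4D array (0-based).
// [[Rcpp::export]]
NumericVector cpp_slice_channels(NumericVector x, int from, int len) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector out = make4(H, W, len, N);
  for (int n = 0; n < N; ++n)
    std::copy(x.begin() + HW * ((size_t)C * n + from),
              x.begin() + HW * ((size_t)C * n + from + len),
              out.begin() + HW * (size_t)len * n);
  return out;
}

// Batch normalization over (H, W, N) per channel.
// [[Rcpp::export]]
List cpp_bn_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                    NumericVector rmean, NumericVector rvar,
                    double momentum, double eps, bool training) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W, CS = HW, NS = HW * C;
  NumericVector out = make4(H, W, C, N);
  NumericVector mu(C), invstd(C);
  NumericVector new_rmean = clone(rmean), new_rvar = clone(rvar);
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double mean, var;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + NS * n + CS * c;
        for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      mean = s / m;
      var = s2 / m - mean * mean;
      if (var < 0) var = 0;
      new_rmean[c] = momentum * rmean[c] + (1 - momentum) * mean;
      new_rvar[c]  = momentum * rvar[c]  + (1 - momentum) * var;
    } else {
      mean = rmean[c]; var = rvar[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    mu[c] = mean; invstd[c] = is;
    const double g = gamma[c] * is, b = beta[c] - gamma[c] * is * mean;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + NS * n + CS * c;
      double* o = out.begin() + NS * n + CS * c;
      for (size_t i = 0; i < HW; ++i) o[i] = g * p[i] + b;
    }
  }
  return List::create(_["out"] = out, _["mean"] = mu, _["invstd"] = invstd,
                      _["rmean"] = new_rmean, _["rvar"] = new_rvar);
}

// [[Rcpp::export]]
List cpp_bn_backward(NumericVector x, NumericVector gout, NumericVector gamma,
                     NumericVector mu, NumericVector invstd) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W, CS = HW, NS = HW * C;
  NumericVector gx = make4(H, W, C, N);
  NumericVector ggamma(C), gbeta(C);
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    const double is = invstd[c], mean = mu[c];
    double sg = 0.0, sgx = 0.0;  // sum(gout), sum(gout * xhat)
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + NS * n + CS * c;
      const double* g = gout.begin() + NS * n + CS * c;
      for (size_t i = 0; i < HW; ++i) {
        sg += g[i];
        sgx += g[i] * (p[i] - mean) * is;
      }
    }
    ggamma[c] = sgx; gbeta[c] = sg;
    const double k = gamma[c] * is;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + NS * n + CS * c;
      const double* g = gout.begin() + NS * n + CS * c;
      double* o = gx.begin() + NS * n + CS * c;
      for (size_t i = 0; i < HW; ++i) {
        const double xh = (p[i] - mean) * is;
        o[i] = k * (g[i] - sg / m - xh * sgx / m);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// 2x2 max pooling, stride 2. Returns pooled map and the 0-based linear
// index (into the full input vector) of each selected maximum.
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial size (%d x %d) not divisible by 2", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out = make4(Ho, Wo, C, N);
  IntegerVector arg(out.size());
  size_t oi = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const size_t i00 = base + 2 * h + (size_t)H * (2 * w);
          size_t best = i00;
          double v = x[i00];
          const size_t cand[3] = {i00 + 1, i00 + H, i00 + H + 1};
          for (int k = 0; k < 3; ++k)
            if (x[cand[k]] > v) { v = x[cand[k]]; best = cand[k]; }
          out[oi] = v; arg[oi] = (int)best; ++oi;
        }
    }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector gout, IntegerVector argmax,
                                    IntegerVector in_dim) {
  NumericVector gx = make4(in_dim[0], in_dim[1], in_dim[2], in_dim[3]);
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[argmax[i]] += gout[i];
  return gx;
}

// 8-connected component labelling of a binary matrix (iterative flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w) || lab(h, w)) continue;
      ++next;
      stack.push_back(h + H * w);
      lab(h, w) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int ph = p % H, pw = p / H;
        for (int dw = -1; dw <= 1; ++dw)
          for (int dh = -1; dh <= 1; ++dh) {
            const int qh = ph + dh, qw = pw + dw;
            if (qh < 0 || qh >= H || qw < 0 || qw >= W) continue;
            if (mask(qh, qw) && !lab(qh, qw)) {
              lab(qh, qw) = next;
              stack.push_back(qh + H * qw);
            }
          }
      }
    }
  return lab;
}

// Square-window median filter with edge replication.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int win) {
  const int H = x.nrow(), W = x.ncol(), r = win / 2;
  NumericMatrix out(H, W);
  std::vector<double> buf;
  buf.reserve((size_t)win * win);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      buf.clear();
      for (int dw = -r; dw <= r; ++dw)
        for (int dh = -r; dh <= r; ++dh) {
          int qh = std::min(std::max(h + dh, 0), H - 1);
          int qw = std::min(std::max(w + dw, 0), W - 1);
          buf.push_back(x(qh, qw));
        }
      std::nth_element(buf.begin(), buf.begin() + buf.size() / 2, buf.end());
      out(h, w) = buf[buf.size() / 2];
    }
  return out;
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// The training loop allocates many multi-megabyte activation arrays per
// step; with glibc's default mmap threshold each one is mapped and
// unmapped by the kernel (page-fault churn dominates the run time). Raise
// the thresholds so large temporaries are recycled on the heap instead.
// [[Rcpp::export]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
#endif
}

// Fused batch normalization + ReLU (every normalization in this
// architecture is immediately followed by ReLU; fusing removes one full
// read/write pass over the activations per block).
// [[Rcpp::export]]
List cpp_bn_relu_forward(NumericVector x, NumericVector gamma,
                         NumericVector beta, NumericVector rmean,
                         NumericVector rvar, double momentum, double eps,
                         bool training) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W, CS = HW, NS = HW * C;
  NumericVector out = make4(H, W, C, N);
  NumericVector mu(C), invstd(C);
  NumericVector new_rmean = clone(rmean), new_rvar = clone(rvar);
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double mean, var;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + NS * n + CS * c;
        for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      mean = s / m;
      var = s2 / m - mean * mean;
      if (var < 0) var = 0;
      new_rmean[c] = momentum * rmean[c] + (1 - momentum) * mean;
      new_rvar[c]  = momentum * rvar[c]  + (1 - momentum) * var;
    } else {
      mean = rmean[c]; var = rvar[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    mu[c] = mean; invstd[c] = is;
    const double g = gamma[c] * is, b = beta[c] - gamma[c] * is * mean;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + NS * n + CS * c;
      double* o = out.begin() + NS * n + CS * c;
      for (size_t i = 0; i < HW; ++i) {
        const double v = g * p[i] + b;
        o[i] = v > 0 ? v : 0.0;
      }
    }
  }
  return List::create(_["out"] = out, _["mean"] = mu, _["invstd"] = invstd,
                      _["rmean"] = new_rmean, _["rvar"] = new_rvar);
}

// [[Rcpp::export]]
List cpp_bn_relu_backward(NumericVector x, NumericVector out,
                          NumericVector gout, NumericVector gamma,
                          NumericVector mu, NumericVector invstd) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W, CS = HW, NS = HW * C;
  NumericVector gx = make4(H, W, C, N);
  NumericVector ggamma(C), gbeta(C);
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    const double is = invstd[c], mean = mu[c];
    double sg = 0.0, sgx = 0.0;  // sums of the ReLU-masked gradient
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + NS * n + CS * c;
      const double* o = out.begin() + NS * n + CS * c;
      const double* g = gout.begin() + NS * n + CS * c;
      for (size_t i = 0; i < HW; ++i) {
        if (o[i] <= 0) continue;
        sg += g[i];
        sgx += g[i] * (p[i] - mean) * is;
      }
    }
    ggamma[c] = sgx; gbeta[c] = sg;
    const double k = gamma[c] * is;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + NS * n + CS * c;
      const double* o = out.begin() + NS * n + CS * c;
      const double* g = gout.begin() + NS * n + CS * c;
      double* gxp = gx.begin() + NS * n + CS * c;
      for (size_t i = 0; i < HW; ++i) {
        const double gm = o[i] > 0 ? g[i] : 0.0;
        const double xh = (p[i] - mean) * is;
        gxp[i] = k * (gm - sg / m - xh * sgx / m);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}
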