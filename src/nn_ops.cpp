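// Core dense tensor kernels for the CNN engine: 2-D convolution and max
// pooling, forward and backward, via per-sample im2col + GEMM.
//
// Layout conventions (R column-major):
//   activations x : array [H, W, C, N]
//   conv weights w: array [kh, kw, Cin, Cout]  (flattened kh fastest)
// im2col produces K x L with K = kh*kw*Cin (matching the weight layout) and
// L = Ho*Wo (ho fastest), so `cols.t() * Wmat` is exactly the [Ho,Wo,Cout]
// output plane in memory order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// colsT is L x K (L = Ho*Wo spatial positions, K = kh*kw*Cin): column krow
// holds one kernel tap across all output positions, so both the gather here
// and the GEMM read/write contiguously.
static inline void im2col_t(const double* x, int H, int W, int C,
                            int kh, int kw, int stride, int pad,
                            int Ho, int Wo, arma::mat& colsT) {
  const int L = Ho * Wo;
  colsT.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int krow = ki + kh * (kj + kw * c);
        double* ccol = colsT.colptr(krow);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wsrc = wo * stride - pad + kj;
          if (wsrc < 0 || wsrc >= W) continue;
          const double* xcol = xc + (size_t)wsrc * H;
          double* dst = ccol + (size_t)Ho * wo;
          const int h0 = std::max(0, (pad - ki + stride - 1) / stride);
          const int h1 = std::min(Ho, (H - 1 + pad - ki) / stride + 1);
          if (stride == 1) {
            for (int ho = h0; ho < h1; ++ho) dst[ho] = xcol[ho - pad + ki];
          } else {
            for (int ho = h0; ho < h1; ++ho) dst[ho] = xcol[ho * stride - pad + ki];
          }
        }
      }
    }
  }
  (void)L;
}

static inline void col2im_t_add(const arma::mat& colsT, int H, int W, int C,
                                int kh, int kw, int stride, int pad,
                                int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int krow = ki + kh * (kj + kw * c);
        const double* ccol = colsT.colptr(krow);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wsrc = wo * stride - pad + kj;
          if (wsrc < 0 || wsrc >= W) continue;
          double* xcol = xc + (size_t)wsrc * H;
          const double* src = ccol + (size_t)Ho * wo;
          const int h0 = std::max(0, (pad - ki + stride - 1) / stride);
          const int h1 = std::min(Ho, (H - 1 + pad - ki) / stride + 1);
          for (int ho = h0; ho < h1; ++ho) xcol[ho * stride - pad + ki] += src[ho];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 Nullable<NumericVector> bias,
                                 int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output size below 1x1");
  const int K = kh * kw * Cin, L = Ho * Wo;

  arma::mat Wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector out((size_t)L * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat colsT(L, K);
  arma::vec b;
  bool has_b = bias.isNotNull();
  if (has_b) b = as<arma::vec>(bias.get());

  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, colsT);
    arma::mat o(out.begin() + (size_t)n * L * Cout, L, Cout, false, true);
    o = colsT * Wmat;
    if (has_b) o.each_row() += b.t();
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dout,
                         bool has_bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector od = dout.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = od[0], Wo = od[1];
  const int K = kh * kw * Cin, L = Ho * Wo;

  arma::mat Wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)K * Cout);
  dw.attr("dim") = wd;
  arma::mat dWmat(dw.begin(), K, Cout, false, true);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat colsT(L, K);

  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad, Ho, Wo, colsT);
    arma::mat dO(const_cast<double*>(dout.begin()) + (size_t)n * L * Cout, L, Cout, false, true);
    dWmat += colsT.t() * dO;
    if (has_bias) db += arma::sum(dO, 0).t();
    arma::mat dcolsT = dO * Wmat.t();
    col2im_t_add(dcolsT, H, W, C, kh, kw, stride, pad, Ho, Wo,
                 dx.begin() + (size_t)n * H * W * C);
  }
  List res = List::create(_["dx"] = dx, _["dw"] = dw);
  if (has_bias) res["db"] = NumericVector(db.begin(), db.end());
  return res;
}

// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("maxpool: output size below 1x1");

  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg((size_t)Ho * Wo * C * N); // 0-based linear index into x, -1 = all padding
  arg.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  size_t oi = 0;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + (size_t)c * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho, ++oi) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int wsrc = wo * stride - pad + kj;
            if (wsrc < 0 || wsrc >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hsrc = ho * stride - pad + ki;
              if (hsrc < 0 || hsrc >= H) continue;
              const double v = xc[hsrc + (size_t)H * wsrc];
              if (v > best) { best = v; besti = hsrc + H * wsrc; }
            }
          }
          // output laid out [Ho,Wo,C,N] but loop order is wo outer, ho inner:
          const size_t oidx = (size_t)ho + Ho * ((size_t)wo + Wo * ((size_t)c + (size_t)C * n));
          out[oidx] = (besti >= 0) ? best : 0.0;
          arg[oidx] = (besti >= 0) ? besti + (int)((size_t)c * H * W) : -1;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(IntegerVector argmax, NumericVector dout,
                                   IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector od = dout.attr("dim");
  const size_t per_out = (size_t)od[0] * od[1] * od[2];
  const size_t per_in = (size_t)H * W * C;
  NumericVector dx(per_in * N);
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n) {
    const double* don = dout.begin() + per_out * n;
    const int* an = argmax.begin() + per_out * n;
    double* dxn = dx.begin() + per_in * n;
    for (size_t i = 0; i < per_out; ++i)
      if (an[i] >= 0) dxn[an[i]] += don[i];
  }
  return dx;
}

// Batch-norm helpers operate per channel on [H,W,C,N].

// [[Rcpp::export]]
List bn_stats_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double M = (double)HW * N;
    mean[c] = s / M;
    double v = s2 / M - mean[c] * mean[c];
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
List bn_forward_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                    NumericVector mean, NumericVector invstd) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector out(x.size()), xhat(x.size());
  out.attr("dim") = xd; xhat.attr("dim") = xd;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = HW * (c + (size_t)C * n);
      const double* p = x.begin() + off;
      double* ph = xhat.begin() + off;
      double* po = out.begin() + off;
      const double m = mean[c], is = invstd[c], g = gamma[c], b = beta[c];
      for (size_t i = 0; i < HW; ++i) {
        const double xh = (p[i] - m) * is;
        ph[i] = xh;
        po[i] = xh * g + b;
      }
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat);
}

// [[Rcpp::export]]
List bn_backward_cpp(NumericVector xhat, NumericVector invstd, NumericVector gamma,
                     NumericVector dout, bool training) {
  IntegerVector xd = xhat.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector dx(xhat.size()); dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = HW * (c + (size_t)C * n);
      const double* ph = xhat.begin() + off;
      const double* pd = dout.begin() + off;
      for (size_t i = 0; i < HW; ++i) { sg += pd[i] * ph[i]; sb += pd[i]; }
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double M = (double)HW * N;
    const double g = gamma[c], is = invstd[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = HW * (c + (size_t)C * n);
      const double* ph = xhat.begin() + off;
      const double* pd = dout.begin() + off;
      double* px = dx.begin() + off;
      if (training) {
        // dxhat = g*dout; dx = invstd/M * (M*dxhat - sum(dxhat) - xhat*sum(dxhat*xhat))
        const double s1 = g * sb, s2 = g * sg;
        for (size_t i = 0; i < HW; ++i)
          px[i] = is / M * (M * g * pd[i] - s1 - ph[i] * s2);
      } else {
        for (size_t i = 0; i < HW; ++i) px[i] = g * pd[i] * is;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector relu_forward_cpp(NumericVector x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double* p = x.begin(); double* o = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) o[i] = p[i] > 0 ? p[i] : 0;
  return out;
}

// [[Rcpp::export]]
NumericVector relu_backward_cpp(NumericVector out, NumericVector dout) {
  NumericVector dx(out.size());
  dx.attr("dim") = dout.attr("dim");
  const double* o = out.begin(); const double* d = dout.begin();
  double* p = dx.begin();
  for (R_xlen_t i = 0; i < out.size(); ++i) p[i] = o[i] > 0 ? d[i] : 0;
  return dx;
}

// Fused batch-norm + ReLU: y = max(0, gamma * (x - mean) * invstd + beta).
// Backward recomputes xhat from the cached input instead of caching it,
// halving the large-array footprint of a CBA block.

// [[Rcpp::export]]
NumericVector bnrelu_forward_cpp(NumericVector x, NumericVector gamma,
                                 NumericVector beta, NumericVector mean,
                                 NumericVector invstd) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector out(x.size());
  out.attr("dim") = xd;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = HW * (c + (size_t)C * n);
      const double* p = x.begin() + off;
      double* po = out.begin() + off;
      const double m = mean[c], is = invstd[c], g = gamma[c], b = beta[c];
      for (size_t i = 0; i < HW; ++i) {
        const double y = (p[i] - m) * is * g + b;
        po[i] = y > 0 ? y : 0;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List bnrelu_backward_cpp(NumericVector x, NumericVector out, NumericVector mean,
                         NumericVector invstd, NumericVector gamma,
                         NumericVector dout, bool training) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = mean[c], is = invstd[c], g = gamma[c];
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = HW * (c + (size_t)C * n);
      const double* px = x.begin() + off;
      const double* po = out.begin() + off;
      const double* pd = dout.begin() + off;
      for (size_t i = 0; i < HW; ++i) {
        if (po[i] > 0) {
          sg += pd[i] * (px[i] - m) * is;
          sb += pd[i];
        }
      }
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double M = (double)HW * N;
    const double s1 = g * sb, s2 = g * sg;
    for (int n = 0; n < N; ++n) {
      const size_t off = HW * (c + (size_t)C * n);
      const double* px = x.begin() + off;
      const double* po = out.begin() + off;
      const double* pd = dout.begin() + off;
      double* pdx = dx.begin() + off;
      if (training) {
        for (size_t i = 0; i < HW; ++i) {
          const double dy = po[i] > 0 ? pd[i] : 0;
          const double xh = (px[i] - m) * is;
          pdx[i] = is / M * (M * g * dy - s1 - xh * s2);
        }
      } else {
        for (size_t i = 0; i < HW; ++i)
          pdx[i] = (po[i] > 0 ? pd[i] : 0) * g * is;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
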