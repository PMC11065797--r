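// Minimal CNN kernels for the residual U-Net: same-padding convolution
// (im2col + GEMM), 2x2 max pooling, 2x2 nearest-neighbour upsampling.
//
// Tensor layout: R numeric arrays dim = c(H, W, C, N) (column-major), so the
// (H x W) plane for fixed channel c and sample n is a contiguous block at
// offset H*W*(c + C*n).  Kernel matrix layout: Cout x (k*k*Cin) with column
// index ci*k*k + dy*k + dx.  The im2col buffer is (H*W) x (k*k*Cin) so that
// every scatter/gather runs down contiguous memory.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static IntegerVector tdims(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d tensor [H,W,C,N]");
  return d;
}

// col: (H*W) x (k*k*C); column r = c*k*k + dy*k + dx holds the input plane
// shifted by (dy-pad, dx-pad), zero-padded
static void im2col(const double* x, int H, int W, int C, int k,
                   arma::mat& col) {
  const int pad = (k - 1) / 2;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* plane = x + (size_t)H * W * c;
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        double* dst = col.colptr(c * k * k + dy * k + dx);
        const int oy = dy - pad, ox = dx - pad;
        const int h0 = std::max(0, -oy), h1 = std::min(H, H - oy);
        for (int w = 0; w < W; ++w) {
          const int wj = w + ox;
          if (wj < 0 || wj >= W) continue;
          const double* src = plane + (size_t)H * wj + oy;
          double* d2 = dst + (size_t)H * w;
          for (int h = h0; h < h1; ++h) d2[h] = src[h];
        }
      }
    }
  }
}

// scatter-add the columns back into an image (transpose of im2col)
static void col2im(const arma::mat& col, int H, int W, int C, int k,
                   double* out) {
  const int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* plane = out + (size_t)H * W * c;
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        const double* src0 = col.colptr(c * k * k + dy * k + dx);
        const int oy = dy - pad, ox = dx - pad;
        const int h0 = std::max(0, -oy), h1 = std::min(H, H - oy);
        for (int w = 0; w < W; ++w) {
          const int wj = w + ox;
          if (wj < 0 || wj >= W) continue;
          double* dst = plane + (size_t)H * wj + oy;
          const double* s2 = src0 + (size_t)H * w;
          for (int h = h0; h < h1; ++h) dst[h] += s2[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(const NumericVector& x, const arma::mat& kmat,
                          const arma::vec& bias, int k) {
  IntegerVector d = tdims(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = kmat.n_rows;
  if ((int)kmat.n_cols != k * k * C) stop("kernel/input channel mismatch");
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const bool has_bias = bias.n_elem > 0;
  const size_t hw = (size_t)H * W;
  if (k == 1) {
    for (int n = 0; n < N; ++n) {
      const arma::mat xin(const_cast<double*>(x.begin()) + hw * C * n, hw, C,
                          false, true);
      arma::mat out(y.begin() + hw * Cout * n, hw, Cout, false, true);
      out = xin * kmat.t();
      if (has_bias) out.each_row() += bias.t();
    }
    return y;
  }
  arma::mat col(hw, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + hw * C * n, H, W, C, k, col);
    arma::mat out(y.begin() + hw * Cout * n, hw, Cout, false, true);
    out = col * kmat.t();
    if (has_bias) out.each_row() += bias.t();
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bw(const NumericVector& x, const arma::mat& kmat,
                 const NumericVector& dy, int k, bool need_dx) {
  IntegerVector d = tdims(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = kmat.n_rows;
  arma::mat dk(Cout, k * k * C, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  const size_t hw = (size_t)H * W;
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector(hw * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  if (k == 1) {
    for (int n = 0; n < N; ++n) {
      const arma::mat xin(const_cast<double*>(x.begin()) + hw * C * n, hw, C,
                          false, true);
      const arma::mat g(const_cast<double*>(dy.begin()) + hw * Cout * n, hw,
                        Cout, false, true);
      dk += g.t() * xin;
      db += arma::sum(g, 0).t();
      if (need_dx) {
        arma::mat dxm(dx.begin() + hw * C * n, hw, C, false, true);
        dxm = g * kmat;
      }
    }
    return List::create(_["dx"] = dx, _["dk"] = dk, _["db"] = db);
  }
  arma::mat col(hw, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + hw * C * n, H, W, C, k, col);
    const arma::mat g(const_cast<double*>(dy.begin()) + hw * Cout * n, hw,
                      Cout, false, true);
    dk += g.t() * col;
    db += arma::sum(g, 0).t();
    if (need_dx) {
      arma::mat dcol = g * kmat;  // (H*W) x (k*k*C)
      col2im(dcol, H, W, C, k, dx.begin() + hw * C * n);
    }
  }
  return List::create(_["dx"] = dx, _["dk"] = dk, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(const NumericVector& x) {
  IntegerVector d = tdims(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // linear index into H*W plane
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const size_t base = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const int li = (2 * h + dh) + H * (2 * w + dw);
              if (plane[li] > best) { best = plane[li]; bi = li; }
            }
          const size_t oo = base + (size_t)Ho * w + h;
          y[oo] = best;
          idx[oo] = bi;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(const NumericVector& dy, const IntegerVector& idx,
                             int H, int W) {
  IntegerVector d = tdims(dy);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* plane = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const size_t base = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (size_t t = 0; t < (size_t)Ho * Wo; ++t)
        plane[idx[base + t]] += dy[base + t];
    }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_fw(const NumericVector& x) {
  IntegerVector d = tdims(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* in = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* out = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = in[h + (size_t)H * w];
          const size_t b = (size_t)2 * h + (size_t)Ho * 2 * w;
          out[b] = v; out[b + 1] = v;
          out[b + Ho] = v; out[b + Ho + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bw(const NumericVector& dy) {
  IntegerVector d = tdims(dy);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* in = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* out = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const size_t b = (size_t)2 * h + (size_t)Ho * 2 * w;
          out[h + (size_t)H * w] = in[b] + in[b + 1] + in[b + Ho] + in[b + Ho + 1];
        }
    }
  return dx;
}

// channel-wise batch statistics: mean and biased variance over (H, W, N)
// [[Rcpp::export]]
List cpp_bn_stats(const NumericVector& x) {
  IntegerVector d = tdims(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  arma::vec mu(C, arma::fill::zeros), v(C, arma::fill::zeros);
  const size_t plane = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      for (size_t t = 0; t < plane; ++t) { s += p[t]; s2 += p[t] * p[t]; }
    }
    const double m = s / (plane * N);
    mu[c] = m;
    v[c] = s2 / (plane * N) - m * m;
  }
  return List::create(_["mean"] = mu, _["var"] = v);
}
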