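// Minimal 2-D convolutional network primitives (forward + backward) used by
// the U-net: same-padding conv via batched im2col + BLAS matmul, 2x2 max
// pooling, and 2x nearest-neighbour upsampling. Arrays are column-major R
// arrays with layout (H, W, C, B).
//
// The im2col buffer is laid out (B*H*W) x (k*k*Cin) so that the innermost
// copy runs down contiguous columns and the convolution is a single GEMM
// per batch.

#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col_batch(const double* x, int H, int W, int Cin, int B,
                         int k, int pad, arma::mat& col) {
  const std::size_t HW = (std::size_t)H * W;
  col.zeros();
  for (int b = 0; b < B; ++b) {
    const double* xb = x + HW * Cin * b;
    for (int c = 0; c < Cin; ++c) {
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int ccol = ki + k * kj + k * k * c;
          double* dst0 = col.colptr(ccol) + HW * b;
          for (int j = 0; j < W; ++j) {
            const int sj = j + kj - pad;
            if (sj < 0 || sj >= W) continue;
            const double* src = xb + (std::size_t)H * (sj + (std::size_t)W * c);
            const int i0 = std::max(0, pad - ki);
            const int i1 = std::min(H, H + pad - ki);
            std::copy(src + i0 + ki - pad, src + i1 + ki - pad,
                      dst0 + (std::size_t)H * j + i0);
          }
        }
      }
    }
  }
}

static void col2im_batch_acc(const arma::mat& gcol, int H, int W, int Cin,
                             int B, int k, int pad, double* gx) {
  const std::size_t HW = (std::size_t)H * W;
  for (int b = 0; b < B; ++b) {
    double* gxb = gx + HW * Cin * b;
    for (int c = 0; c < Cin; ++c) {
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int ccol = ki + k * kj + k * k * c;
          const double* src0 = gcol.colptr(ccol) + HW * b;
          for (int j = 0; j < W; ++j) {
            const int sj = j + kj - pad;
            if (sj < 0 || sj >= W) continue;
            double* dst = gxb + (std::size_t)H * (sj + (std::size_t)W * c);
            const int i0 = std::max(0, pad - ki);
            const int i1 = std::min(H, H + pad - ki);
            const double* src = src0 + (std::size_t)H * j;
            for (int i = i0; i < i1; ++i) dst[i + ki - pad] += src[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = (k - 1) / 2;
  const std::size_t HW = (std::size_t)H * W;
  arma::mat Wmat(const_cast<double*>(w.begin()), k * k * Cin, Cout, false);
  NumericVector y(HW * Cout * B);
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);
  arma::mat col(HW * B, k * k * Cin);
  im2col_batch(x.begin(), H, W, Cin, B, k, pad, col);
  arma::mat Y = col * Wmat;  // (B*H*W) x Cout
  for (int b = 0; b < B; ++b) {
    double* yb = y.begin() + HW * Cout * b;
    for (int c = 0; c < Cout; ++c) {
      const double* src = Y.colptr(c) + HW * b;
      const double bc = bias[c];
      double* dst = yb + HW * c;
      for (std::size_t i = 0; i < HW; ++i) dst[i] = src[i] + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = (k - 1) / 2;
  const std::size_t HW = (std::size_t)H * W;
  arma::mat Wmat(const_cast<double*>(w.begin()), k * k * Cin, Cout, false);
  NumericVector gx(HW * Cin * B);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, B);
  NumericVector gw((std::size_t)k * k * Cin * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat gWmat(gw.begin(), k * k * Cin, Cout, false);

  // reshape gy into the (B*H*W) x Cout layout matching the im2col buffer
  arma::mat Gy(HW * B, Cout);
  for (int b = 0; b < B; ++b) {
    const double* gyb = gy.begin() + HW * Cout * b;
    for (int c = 0; c < Cout; ++c) {
      std::copy(gyb + HW * c, gyb + HW * (c + 1), Gy.colptr(c) + HW * b);
      double s = 0;
      for (std::size_t i = 0; i < HW; ++i) s += gyb[HW * c + i];
      gb[c] += s;
    }
  }
  arma::mat col(HW * B, k * k * Cin);
  im2col_batch(x.begin(), H, W, Cin, B, k, pad, col);
  gWmat = col.t() * Gy;
  arma::mat gcol = Gy * Wmat.t();  // (B*H*W) x (k*k*Cin)
  std::fill(gx.begin(), gx.end(), 0.0);
  col2im_batch_acc(gcol, H, W, Cin, B, k, pad, gx.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((std::size_t)Ho * Wo * C * B);
  IntegerVector idx((std::size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  std::size_t o = 0;
  for (int b = 0; b < B; ++b) {
    const std::size_t xoff = (std::size_t)H * W * C * b;
    for (int c = 0; c < C; ++c) {
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i, ++o) {
          double best = -1e300;
          std::size_t bi = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const std::size_t lin = (2 * i + di) +
                (std::size_t)H * (2 * j + dj) + (std::size_t)H * W * c;
              const double v = x[xoff + lin];
              if (v > best) { best = v; bi = lin; }
            }
          }
          y[o] = best;
          idx[o] = (int)bi;  // offset within one sample (H*W*C fits in int)
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector gy, int H,
                               int W) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], B = yd[3];
  NumericVector gx((std::size_t)H * W * C * B);
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  std::fill(gx.begin(), gx.end(), 0.0);
  const std::size_t per = (std::size_t)Ho * Wo * C;
  for (int b = 0; b < B; ++b) {
    const std::size_t xoff = (std::size_t)H * W * C * b;
    for (std::size_t o = 0; o < per; ++o) {
      gx[xoff + (std::size_t)idx[per * b + o]] += gy[per * b + o];
    }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((std::size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  std::size_t s = 0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const std::size_t yoff = (std::size_t)Ho * Wo * (c + (std::size_t)C * b);
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i, ++s) {
          const double v = x[s];
          const std::size_t base = (std::size_t)2 * i +
            (std::size_t)Ho * 2 * j + yoff;
          y[base] = v;
          y[base + 1] = v;
          y[base + Ho] = v;
          y[base + Ho + 1] = v;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gy) {
  IntegerVector yd = gy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], B = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector gx((std::size_t)H * W * C * B);
  gx.attr("dim") = IntegerVector::create(H, W, C, B);
  std::size_t s = 0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const std::size_t yoff = (std::size_t)Ho * Wo * (c + (std::size_t)C * b);
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i, ++s) {
          const std::size_t base = (std::size_t)2 * i +
            (std::size_t)Ho * 2 * j + yoff;
          gx[s] = gy[base] + gy[base + 1] + gy[base + Ho] + gy[base + Ho + 1];
        }
      }
    }
  }
  return gx;
}
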