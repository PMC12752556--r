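// Low-level tensor kernels for the compact convolutional networks.
// Layout conventions match R arrays: an image tensor is [H, W, C]
// (column-major, row index fastest), mapped onto arma::cube with
// n_rows = H, n_cols = W, n_slices = C. Dense convolutions use
// im2col + BLAS matmul; depthwise convolutions use direct loops
// (channel counts are small throughout).

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build the im2col matrix in (N x K) layout: rows are output positions
// (hout fastest), columns are (dh, dw, ci) with dh fastest — matching the
// R flattening of a [kh, kw, cin, cout] weight array. The inner copy along
// hout is contiguous on both sides for stride 1, so it reduces to memcpy.
static arma::mat im2col(const arma::cube& x, int kh, int kw,
                         int stride, int pad, int dil,
                         int Hout, int Wout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(Hout * Wout, kh * kw * C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * ci);
        double* colbase = cols.colptr(r);
        const double* slice = x.slice_memptr(ci);
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride - pad + dw * dil;
          if (wi < 0 || wi >= W) continue;
          const int off = dh * dil - pad;
          if (stride == 1) {
            const int lo = std::max(0, -off);
            const int hiEnd = std::min(Hout, H - off);
            if (hiEnd > lo)
              std::memcpy(colbase + lo + (size_t)Hout * wo,
                          slice + lo + off + (size_t)H * wi,
                          (hiEnd - lo) * sizeof(double));
          } else {
            for (int ho = 0; ho < Hout; ++ho) {
              const int hi = ho * stride + off;
              if (hi < 0 || hi >= H) continue;
              colbase[ho + (size_t)Hout * wo] = slice[hi + (size_t)H * wi];
            }
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add columns back into an image tensor (adjoint of im2col).
static arma::cube col2im(const arma::mat& cols, int H, int W, int C,
                         int kh, int kw, int stride, int pad, int dil,
                         int Hout, int Wout) {
  arma::cube xf(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * ci);
        const double* colbase = cols.colptr(r);
        double* slice = xf.slice_memptr(ci);
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride - pad + dw * dil;
          if (wi < 0 || wi >= W) continue;
          const int off = dh * dil - pad;
          if (stride == 1) {
            const int lo = std::max(0, -off);
            const int hiEnd = std::min(Hout, H - off);
            const double* src = colbase + lo + (size_t)Hout * wo;
            double* dst = slice + lo + off + (size_t)H * wi;
            for (int k = 0; k < hiEnd - lo; ++k) dst[k] += src[k];
          } else {
            for (int ho = 0; ho < Hout; ++ho) {
              const int hi = ho * stride + off;
              if (hi < 0 || hi >= H) continue;
              slice[hi + (size_t)H * wi] += colbase[ho + (size_t)Hout * wo];
            }
          }
        }
      }
    }
  }
  return xf;
}

static inline int out_size(int n, int k, int stride, int pad, int dil) {
  return (n + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Lightweight no-copy view of an R [H, W, C] array.
static arma::cube cube_view(const NumericVector& v) {
  IntegerVector d = v.attr("dim");
  return arma::cube(const_cast<double*>(v.begin()), d[0], d[1], d[2],
                    false, true);
}

// Forward convolution; optionally applies ReLU in place on the output
// (relu != 0), so conv + activation costs a single R allocation.
// [[Rcpp::export(name = ".cpp_conv_fwd")]]
arma::cube cpp_conv_fwd(const NumericVector& xv, const arma::mat& w,
                        const arma::vec& b, int kh, int kw,
                        int stride, int pad, int dil, int relu = 0) {
  arma::cube x = cube_view(xv);
  const int Hout = out_size(x.n_rows, kh, stride, pad, dil);
  const int Wout = out_size(x.n_cols, kw, stride, pad, dil);
  const int Cout = w.n_cols;
  arma::mat cols = im2col(x, kh, kw, stride, pad, dil, Hout, Wout);
  arma::mat out = cols * w;                // (Hout*Wout) x Cout
  out.each_row() += b.t();
  if (relu) out.transform([](double v) { return v > 0 ? v : 0.0; });
  return arma::cube(out.memptr(), Hout, Wout, Cout);
}

// Backward convolution. When the layer was fused with ReLU, pass the
// cached activated output y: the incoming gradient is masked by y > 0
// inside C++ (no extra R allocation).
// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(const NumericVector& xv, const arma::mat& w,
                  const NumericVector& goutv, int kh, int kw,
                  int stride, int pad, int dil,
                  Rcpp::Nullable<Rcpp::NumericVector> yv = R_NilValue) {
  arma::cube x = cube_view(xv);
  arma::cube gout = cube_view(goutv);
  const int Hout = gout.n_rows, Wout = gout.n_cols, Cout = gout.n_slices;
  arma::mat gmat(const_cast<double*>(gout.memptr()), Hout * Wout, Cout,
                 false, true);
  arma::mat gmasked;
  if (yv.isNotNull()) {
    NumericVector yy(yv);
    const double* py = yy.begin();
    gmasked = gmat;  // copy, then mask by the ReLU derivative
    double* pg = gmasked.memptr();
    for (size_t i = 0; i < gmasked.n_elem; ++i) if (py[i] <= 0) pg[i] = 0;
  }
  const arma::mat& g = yv.isNotNull() ? gmasked : gmat;
  arma::mat cols = im2col(x, kh, kw, stride, pad, dil, Hout, Wout);
  arma::mat gw = cols.t() * g;             // (kh*kw*Cin) x Cout
  arma::vec gb = arma::sum(g, 0).t();
  arma::mat gcols = g * w.t();             // N x (kh*kw*Cin)
  arma::cube gx = col2im(gcols, x.n_rows, x.n_cols, x.n_slices,
                         kh, kw, stride, pad, dil, Hout, Wout);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Depthwise convolution: one k x k filter per channel, stride 1, 'same'
// padding. Implemented as shifted-segment AXPY passes: for each kernel
// offset, the valid output rows form a contiguous column segment on both
// sides, so the inner loop is branch-free and cache-friendly.
// [[Rcpp::export(name = ".cpp_dwconv_fwd")]]
arma::cube cpp_dwconv_fwd(const NumericVector& xv, const arma::cube& w,
                          const arma::vec& b, int pad, int dil) {
  arma::cube x = cube_view(xv);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int kh = w.n_rows, kw = w.n_cols;
  arma::cube y(H, W, C);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.slice_memptr(c);
    double* ys = y.slice_memptr(c);
    std::fill(ys, ys + (size_t)H * W, b(c));
    for (int dw = 0; dw < kw; ++dw) {
      const int woff = dw * dil - pad;
      const int wlo = std::max(0, -woff), whi = std::min(W, W - woff);
      for (int dh = 0; dh < kh; ++dh) {
        const int hoff = dh * dil - pad;
        const int hlo = std::max(0, -hoff), hhi = std::min(H, H - hoff);
        const double wk = w(dh, dw, c);
        if (wk == 0.0 || hhi <= hlo) continue;
        for (int wo = wlo; wo < whi; ++wo) {
          const double* src = xs + (size_t)H * (wo + woff) + hlo + hoff;
          double* dst = ys + (size_t)H * wo + hlo;
          for (int k = 0; k < hhi - hlo; ++k) dst[k] += wk * src[k];
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_dwconv_bwd")]]
List cpp_dwconv_bwd(const NumericVector& xv, const arma::cube& w,
                    const NumericVector& goutv, int pad, int dil) {
  arma::cube x = cube_view(xv);
  arma::cube gout = cube_view(goutv);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int kh = w.n_rows, kw = w.n_cols;
  arma::cube gx(H, W, C, arma::fill::zeros);
  arma::cube gw(kh, kw, C, arma::fill::zeros);
  arma::vec gb(C);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.slice_memptr(c);
    const double* gs = gout.slice_memptr(c);
    double* gxs = gx.slice_memptr(c);
    for (int dw = 0; dw < kw; ++dw) {
      const int woff = dw * dil - pad;
      const int wlo = std::max(0, -woff), whi = std::min(W, W - woff);
      for (int dh = 0; dh < kh; ++dh) {
        const int hoff = dh * dil - pad;
        const int hlo = std::max(0, -hoff), hhi = std::min(H, H - hoff);
        if (hhi <= hlo) { gw(dh, dw, c) = 0.0; continue; }
        const double wk = w(dh, dw, c);
        double acc = 0.0;
        for (int wo = wlo; wo < whi; ++wo) {
          const double* g = gs + (size_t)H * wo + hlo;
          const double* xp = xs + (size_t)H * (wo + woff) + hlo + hoff;
          double* gxp = gxs + (size_t)H * (wo + woff) + hlo + hoff;
          for (int k = 0; k < hhi - hlo; ++k) {
            acc += g[k] * xp[k];
            gxp[k] += wk * g[k];
          }
        }
        gw(dh, dw, c) = acc;
      }
    }
    gb(c) = arma::accu(gout.slice(c));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled values and flat argmax
// indices (0-based into the input slice) for the backward pass.
// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(const NumericVector& xv) {
  arma::cube x = cube_view(xv);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int bh = 2 * ho, bw = 2 * wo;
        double best = x(bh, bw, c);
        int bi = bh + H * bw;
        for (int dw = 0; dw < 2; ++dw) {
          for (int dh = 0; dh < 2; ++dh) {
            double v = x(bh + dh, bw + dw, c);
            if (v > best) { best = v; bi = (bh + dh) + H * (bw + dw); }
          }
        }
        y(ho, wo, c) = best;
        idx(ho, wo, c) = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
arma::cube cpp_maxpool2_bwd(const arma::ucube& idx, const arma::cube& gout,
                            int H, int W) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, C = gout.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* slice = gx.slice_memptr(c);
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        slice[idx(ho, wo, c)] += gout(ho, wo, c);
  }
  return gx;
}

// Nearest-neighbour upsampling by an integer factor.
// [[Rcpp::export(name = ".cpp_upsample_fwd")]]
arma::cube cpp_upsample_fwd(const NumericVector& xv, int f) {
  arma::cube x = cube_view(xv);
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(H * f, W * f, C);
  for (int c = 0; c < C; ++c) {
    const double* src = x.slice_memptr(c);
    double* dst = y.slice_memptr(c);
    for (int wo = 0; wo < W * f; ++wo) {
      const double* scol = src + (size_t)H * (wo / f);
      double* dcol = dst + (size_t)H * f * wo;
      for (int h = 0; h < H; ++h) {
        const double v = scol[h];
        for (int k = 0; k < f; ++k) dcol[h * f + k] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample_bwd")]]
arma::cube cpp_upsample_bwd(const NumericVector& goutv, int f) {
  arma::cube gout = cube_view(goutv);
  const int Ho = gout.n_rows / f, Wo = gout.n_cols / f, C = gout.n_slices;
  arma::cube gx(Ho, Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = gout.slice_memptr(c);
    double* dst = gx.slice_memptr(c);
    for (int w = 0; w < Wo * f; ++w) {
      const double* scol = src + (size_t)Ho * f * w;
      double* dcol = dst + (size_t)Ho * (w / f);
      for (int h = 0; h < Ho * f; ++h) dcol[h / f] += scol[h];
    }
  }
  return gx;
}

// Elementwise max(x, 0); backward uses y > 0.
// [[Rcpp::export(name = ".cpp_relu_fwd")]]
NumericVector cpp_relu_fwd(const NumericVector& x) {
  NumericVector y(clone(x));
  double* p = y.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i) if (p[i] < 0) p[i] = 0;
  return y;
}

// [[Rcpp::export(name = ".cpp_relu_bwd")]]
NumericVector cpp_relu_bwd(const NumericVector& y, const NumericVector& g) {
  NumericVector gx(clone(g));
  const double* py = y.begin();
  double* p = gx.begin();
  for (R_xlen_t i = 0; i < gx.size(); ++i) if (py[i] <= 0) p[i] = 0;
  return gx;
}

// Concatenate [H, W, Ci] arrays along the channel axis.
// [[Rcpp::export(name = ".cpp_concat3")]]
NumericVector cpp_concat3(const List& parts) {
  const int np = parts.size();
  NumericVector first = parts[0];
  IntegerVector d0 = first.attr("dim");
  int ctot = 0;
  for (int i = 0; i < np; ++i) {
    NumericVector p = parts[i];
    IntegerVector d = p.attr("dim");
    ctot += d[2];
  }
  NumericVector out((R_xlen_t)d0[0] * d0[1] * ctot);
  double* dst = out.begin();
  for (int i = 0; i < np; ++i) {
    NumericVector p = parts[i];
    std::memcpy(dst, p.begin(), p.size() * sizeof(double));
    dst += p.size();
  }
  out.attr("dim") = IntegerVector::create(d0[0], d0[1], ctot);
  return out;
}
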