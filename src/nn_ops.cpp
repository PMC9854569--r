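#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tensors are R arrays with dim (H, W, C), column-major; weights for a
// k x k convolution have dim (k, k, Cin, Cout).  All convolutions are
// stride 1, zero-padded "same", optionally dilated.

static arma::mat im2col(const arma::cube& x, int k, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = dil * (k - 1) / 2;
  arma::mat out(H * (long long)W, (long long)k * k * C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        long long col = (long long)c * k * k + kj * k + ki;
        double* dst = out.colptr(col);
        int oi = ki * dil - pad, oj = kj * dil - pad;
        for (int j = 0; j < W; ++j) {
          int sj = j + oj;
          if (sj < 0 || sj >= W) {
            std::fill(dst + (long long)j * H, dst + (long long)(j + 1) * H, 0.0);
            continue;
          }
          const double* src = xc.colptr(sj);
          for (int i = 0; i < H; ++i) {
            int si = i + oi;
            dst[(long long)j * H + i] =
                (si < 0 || si >= H) ? 0.0 : src[si];
          }
        }
      }
    }
  }
  return out;
}

static void col2im_add(const arma::mat& cols, arma::cube& gx, int k, int dil) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  const int pad = dil * (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    arma::mat& xc = gx.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        long long col = (long long)c * k * k + kj * k + ki;
        const double* src = cols.colptr(col);
        int oi = ki * dil - pad, oj = kj * dil - pad;
        for (int j = 0; j < W; ++j) {
          int sj = j + oj;
          if (sj < 0 || sj >= W) continue;
          double* dst = xc.colptr(sj);
          for (int i = 0; i < H; ++i) {
            int si = i + oi;
            if (si >= 0 && si < H) dst[si] += src[(long long)j * H + i];
          }
        }
      }
    }
  }
}

static arma::cube as_cube(const NumericVector& x) {
  IntegerVector d(x.attr("dim"));
  arma::cube out(REAL(x), d[0], d[1], d.size() == 3 ? d[2] : 1, false, true);
  return out;
}

static NumericVector cube_to_r(const arma::cube& x) {
  NumericVector out(x.begin(), x.end());
  out.attr("dim") = IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(const NumericVector& x, const NumericVector& w,
                         const NumericVector& b, int dil) {
  arma::cube xc = as_cube(x);
  IntegerVector wd(w.attr("dim"));
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  arma::mat wm(REAL(NumericVector(w)), k * k * Cin, Cout);
  arma::mat y;
  if (k == 1) {
    arma::mat xm(xc.memptr(), xc.n_rows * xc.n_cols, Cin, false, true);
    y = xm * wm;
  } else {
    y = im2col(xc, k, dil) * wm;
  }
  arma::rowvec bv(REAL(NumericVector(b)), Cout);
  y.each_row() += bv;
  arma::cube yc(y.memptr(), xc.n_rows, xc.n_cols, Cout, false, true);
  return cube_to_r(yc);
}

// [[Rcpp::export]]
List cpp_conv2d_bw(const NumericVector& x, const NumericVector& w,
                   const NumericVector& gy, int dil) {
  arma::cube xc = as_cube(x);
  arma::cube gyc = as_cube(gy);
  IntegerVector wd(w.attr("dim"));
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const long long HW = (long long)xc.n_rows * xc.n_cols;
  arma::mat wm(REAL(NumericVector(w)), k * k * Cin, Cout);
  arma::mat gym(gyc.memptr(), HW, Cout, false, true);
  arma::mat gw;
  arma::cube gxc(xc.n_rows, xc.n_cols, Cin, arma::fill::zeros);
  if (k == 1) {
    arma::mat xm(xc.memptr(), HW, Cin, false, true);
    gw = xm.t() * gym;
    arma::mat gxm = gym * wm.t();
    std::copy(gxm.begin(), gxm.end(), gxc.begin());
  } else {
    arma::mat cols = im2col(xc, k, dil);
    gw = cols.t() * gym;
    arma::mat gcols = gym * wm.t();
    col2im_add(gcols, gxc, k, dil);
  }
  arma::rowvec gb = arma::sum(gym, 0);
  NumericVector gwr(gw.begin(), gw.end());
  gwr.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  return List::create(_["gx"] = cube_to_r(gxc), _["gw"] = gwr,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
List cpp_maxpool2(const NumericVector& x) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  const int H2 = H / 2, W2 = W / 2;
  NumericVector y(Dimension(H2, W2, C));
  IntegerVector idx(H2 * (R_xlen_t)W2 * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        double best = R_NegInf; int bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            int si = 2 * i + di, sj = 2 * j + dj;
            double v = xc(si, sj, c);
            if (v > best) { best = v; bi = si + sj * H + c * H * W; }
          }
        R_xlen_t o = i + (R_xlen_t)j * H2 + (R_xlen_t)c * H2 * W2;
        y[o] = best; idx[o] = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(const NumericVector& gy, const IntegerVector& idx,
                              int H, int W, int C) {
  NumericVector gx(Dimension(H, W, C));
  const R_xlen_t n = gy.size();
  for (R_xlen_t o = 0; o < n; ++o) gx[idx[o]] += gy[o];
  return gx;
}

// Bilinear resize (align_corners = FALSE).  Used forward-only for the
// shallow-branch image pyramid and for data augmentation.
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(const NumericVector& x, int H2, int W2) {
  arma::cube xc = as_cube(x);
  const int H = xc.n_rows, W = xc.n_cols, C = xc.n_slices;
  NumericVector y(Dimension(H2, W2, C));
  double sr = (double)H / H2, sc = (double)W / W2;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W2; ++j) {
      double fc = (j + 0.5) * sc - 0.5;
      int j0 = (int)std::floor(fc);
      double wc = fc - j0;
      int j0c = std::min(std::max(j0, 0), W - 1);
      int j1c = std::min(std::max(j0 + 1, 0), W - 1);
      for (int i = 0; i < H2; ++i) {
        double fr = (i + 0.5) * sr - 0.5;
        int i0 = (int)std::floor(fr);
        double wr = fr - i0;
        int i0c = std::min(std::max(i0, 0), H - 1);
        int i1c = std::min(std::max(i0 + 1, 0), H - 1);
        double v = (1 - wr) * ((1 - wc) * xc(i0c, j0c, c) + wc * xc(i0c, j1c, c)) +
                   wr * ((1 - wc) * xc(i1c, j0c, c) + wc * xc(i1c, j1c, c));
        y[i + (R_xlen_t)j * H2 + (R_xlen_t)c * H2 * W2] = v;
      }
    }
  }
  return y;
}

// Adjoint of 2x bilinear upsampling (scatter with the same weights).
// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(const NumericVector& gy) {
  arma::cube gyc = as_cube(gy);
  const int H2 = gyc.n_rows, W2 = gyc.n_cols, C = gyc.n_slices;
  const int H = H2 / 2, W = W2 / 2;
  NumericVector gx(Dimension(H, W, C));
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W2; ++j) {
      double fc = (j + 0.5) * 0.5 - 0.5;
      int j0 = (int)std::floor(fc);
      double wc = fc - j0;
      int j0c = std::min(std::max(j0, 0), W - 1);
      int j1c = std::min(std::max(j0 + 1, 0), W - 1);
      for (int i = 0; i < H2; ++i) {
        double fr = (i + 0.5) * 0.5 - 0.5;
        int i0 = (int)std::floor(fr);
        double wr = fr - i0;
        int i0c = std::min(std::max(i0, 0), H - 1);
        int i1c = std::min(std::max(i0 + 1, 0), H - 1);
        double g = gyc(i, j, c);
        R_xlen_t base = (R_xlen_t)c * H * W;
        gx[i0c + (R_xlen_t)j0c * H + base] += (1 - wr) * (1 - wc) * g;
        gx[i0c + (R_xlen_t)j1c * H + base] += (1 - wr) * wc * g;
        gx[i1c + (R_xlen_t)j0c * H + base] += wr * (1 - wc) * g;
        gx[i1c + (R_xlen_t)j1c * H + base] += wr * wc * g;
      }
    }
  }
  return gx;
}

// Sample an image at continuous source coordinates (geometric warps).
// mode 0 = bilinear (images), 1 = nearest (label maps).  Out-of-image
// samples give 0.
// [[Rcpp::export]]
NumericMatrix cpp_warp(const NumericMatrix& img, const NumericMatrix& rowmap,
                       const NumericMatrix& colmap, int mode) {
  const int H = img.nrow(), W = img.ncol();
  const int H2 = rowmap.nrow(), W2 = rowmap.ncol();
  NumericMatrix out(H2, W2);
  for (int j = 0; j < W2; ++j) {
    for (int i = 0; i < H2; ++i) {
      double fr = rowmap(i, j), fc = colmap(i, j);
      if (mode == 1) {
        int ri = (int)std::lround(fr), ci = (int)std::lround(fc);
        out(i, j) = (ri < 0 || ri >= H || ci < 0 || ci >= W) ? 0.0
                                                             : img(ri, ci);
      } else {
        if (fr < 0 || fr > H - 1 || fc < 0 || fc > W - 1) { out(i, j) = 0.0; continue; }
        int i0 = (int)std::floor(fr), j0 = (int)std::floor(fc);
        int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
        double wr = fr - i0, wc = fc - j0;
        out(i, j) = (1 - wr) * ((1 - wc) * img(i0, j0) + wc * img(i0, j1)) +
                    wr * ((1 - wc) * img(i1, j0) + wc * img(i1, j1));
      }
    }
  }
  return out;
}
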