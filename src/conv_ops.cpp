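// Convolution and pooling inner loops for the 2D EEG CNN.
// Layout convention (column-major, matching R arrays): activations are
// (H, W, C, B) = (time, electrode, feature map, batch); conv weights are a
// (kh*kw*Cin) x Cout matrix whose row index is ki + kh*(kj + kw*ci), i.e. the
// col-major flattening of an R array dim c(kh, kw, Cin, Cout). Convolutions
// are stride 1 with zero "same" padding (odd kernels only).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_fill(const double* xb, arma::mat& P,
                        int H, int W, int Cin, int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = xb + (size_t)H * W * ci;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ci * kh * kw + kj * kh + ki;
        double* Pcol = P.colptr(col);
        const int di = ki - ph, dj = kj - pw;
        for (int j = 0; j < W; ++j) {
          double* Pj = Pcol + (size_t)H * j;
          const int sj = j + dj;
          if (sj < 0 || sj >= W) { std::fill(Pj, Pj + H, 0.0); continue; }
          const double* xcol = xc + (size_t)H * sj;
          const int lo = std::max(0, -di), hi = std::min(H, H - di);
          for (int i = 0; i < lo; ++i) Pj[i] = 0.0;
          for (int i = lo; i < hi; ++i) Pj[i] = xcol[i + di];
          for (int i = hi; i < H; ++i) Pj[i] = 0.0;
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, const arma::mat& Wm,
                             const arma::vec& b, int kh, int kw) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int Cout = Wm.n_cols, HW = H * W;
  if ((int)Wm.n_rows != kh * kw * Cin) stop("conv weight shape mismatch");
  NumericVector y((size_t)HW * Cout * B);
  arma::mat P(HW, kh * kw * Cin);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int bb = 0; bb < B; ++bb) {
    im2col_fill(xp + (size_t)HW * Cin * bb, P, H, W, Cin, kh, kw);
    arma::mat Y(yp + (size_t)HW * Cout * bb, HW, Cout, false, true);
    Y = P * Wm;
    Y.each_row() += b.t();
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, const arma::mat& Wm,
                    NumericVector gy, int kh, int kw) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int Cout = Wm.n_cols, HW = H * W;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  NumericVector gx(x.size());
  arma::mat gW(Wm.n_rows, Wm.n_cols, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::mat P(HW, kh * kw * Cin), gP(HW, kh * kw * Cin);
  const double* xp = x.begin();
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  for (int bb = 0; bb < B; ++bb) {
    im2col_fill(xp + (size_t)HW * Cin * bb, P, H, W, Cin, kh, kw);
    const arma::mat G(const_cast<double*>(gyp + (size_t)HW * Cout * bb),
                      HW, Cout, false, true);
    gW += P.t() * G;
    gb += arma::sum(G, 0).t();
    gP = G * Wm.t();
    // col2im: scatter-add gP back onto the input gradient
    double* gxb = gxp + (size_t)HW * Cin * bb;
    for (int ci = 0; ci < Cin; ++ci) {
      double* gxc = gxb + (size_t)HW * ci;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const int col = ci * kh * kw + kj * kh + ki;
          const double* Pcol = gP.colptr(col);
          const int di = ki - ph, dj = kj - pw;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dj;
            if (sj < 0 || sj >= W) continue;
            const double* Pj = Pcol + (size_t)H * j;
            double* gxcol = gxc + (size_t)H * sj;
            const int lo = std::max(0, -di), hi = std::min(H, H - di);
            for (int i = lo; i < hi; ++i) gxcol[i + di] += Pj[i];
          }
        }
      }
    }
  }
  gx.attr("dim") = xd;
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int ph, int pw) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  if (H % ph != 0 || W % pw != 0) stop("pooling requires divisible spatial dims");
  const int Ho = H / ph, Wo = W / pw;
  NumericVector y((size_t)Ho * Wo * C * B);
  IntegerVector idx(y.size());  // 0-based linear index into x of each argmax
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t o = 0;
  for (int bb = 0; bb < B; ++bb) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)bb * C + c) * H * W;
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io, ++o) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bidx = 0;
          for (int dj = 0; dj < pw; ++dj) {
            for (int di = 0; di < ph; ++di) {
              const size_t xi = base + (size_t)(jo * pw + dj) * H + (io * ph + di);
              if (xp[xi] > best) { best = xp[xi]; bidx = xi; }  // first-max tie rule
            }
          }
          yp[o] = best;
          ip[o] = (int)bidx;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  double* gxp = gx.begin();
  const double* gyp = gy.begin();
  const int* ip = idx.begin();
  for (R_xlen_t k = 0; k < gy.size(); ++k) gxp[ip[k]] += gyp[k];
  gx.attr("dim") = xdim;
  return gx;
}

// y[, j] = x[, j] * mul[j] + add[j], treating x as an nrow x (len/nrow) matrix.
// Used for the per-feature-map scalings of batch norm and structured dropout
// without allocating sweep() temporaries.
// [[Rcpp::export]]
NumericVector col_affine_cpp(NumericVector x, int nrow,
                             NumericVector mul, NumericVector add) {
  const R_xlen_t n = x.size();
  const R_xlen_t ncol = n / nrow;
  NumericVector y(n);
  const bool smul = mul.size() == 1, sadd = add.size() == 1;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t j = 0; j < ncol; ++j) {
    const double m = smul ? mul[0] : mul[j];
    const double a = sadd ? add[0] : add[j];
    const double* xj = xp + j * nrow;
    double* yj = yp + j * nrow;
    for (int i = 0; i < nrow; ++i) yj[i] = xj[i] * m + a;
  }
  return y;
}

// out[, j] = ax[j] * x[, j] + ay[j] * y[, j] + add[j]
// [[Rcpp::export]]
NumericVector col_affine2_cpp(NumericVector x, NumericVector y, int nrow,
                              NumericVector ax, NumericVector ay,
                              NumericVector add) {
  const R_xlen_t n = x.size();
  const R_xlen_t ncol = n / nrow;
  NumericVector out(n);
  const double* xp = x.begin();
  const double* yp = y.begin();
  double* op = out.begin();
  for (R_xlen_t j = 0; j < ncol; ++j) {
    const double a = ax[j], b = ay[j], c = add[j];
    const double* xj = xp + j * nrow;
    const double* yj = yp + j * nrow;
    double* oj = op + j * nrow;
    for (int i = 0; i < nrow; ++i) oj[i] = a * xj[i] + b * yj[i] + c;
  }
  return out;
}

// per-column dot products: sum_i x[i, j] * y[i, j]
// [[Rcpp::export]]
NumericVector col_dot_cpp(NumericVector x, NumericVector y, int nrow) {
  const R_xlen_t ncol = x.size() / nrow;
  NumericVector out(ncol);
  const double* xp = x.begin();
  const double* yp = y.begin();
  for (R_xlen_t j = 0; j < ncol; ++j) {
    const double* xj = xp + j * nrow;
    const double* yj = yp + j * nrow;
    double s = 0;
    for (int i = 0; i < nrow; ++i) s += xj[i] * yj[i];
    out[j] = s;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// gradient gated on the forward OUTPUT (y > 0 iff the unit was active)
// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector y, NumericVector g) {
  NumericVector out(g.size());
  const double* yp = y.begin();
  const double* gp = g.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) op[i] = yp[i] > 0 ? gp[i] : 0;
  return out;
}
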