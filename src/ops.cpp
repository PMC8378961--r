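// Convolution / transposed-convolution kernels for MCRN feature maps.
//
// Feature maps are R arrays laid out (H, W, C) or (H, W, C, B), column-major.
// Weights are (k, k, Cin, Cout).  Both directions (forward and gradient) are
// computed as one GEMM per kernel tap over a gathered/scattered pixel matrix,
// so the arithmetic cost is exactly H*W*k^2*Cin*Cout multiply-adds and the
// heavy lifting happens in BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims(const NumericVector& x, int& H, int& W, int& C, int& B,
                     bool& was3d) {
  if (!x.hasAttribute("dim")) stop("feature array must have a dim attribute");
  IntegerVector d = x.attr("dim");
  if (d.size() == 3) {
    H = d[0]; W = d[1]; C = d[2]; B = 1; was3d = true;
  } else if (d.size() == 4) {
    H = d[0]; W = d[1]; C = d[2]; B = d[3]; was3d = false;
  } else {
    stop("feature array must be 3-D (H,W,C) or 4-D (H,W,C,B)");
  }
}

static void get_wdims(const NumericVector& w, int Cin_expected, int& k, int& Cin,
                      int& Cout) {
  if (!w.hasAttribute("dim")) stop("weight array must have a dim attribute");
  IntegerVector d = w.attr("dim");
  if (d.size() != 4) stop("weights must be a 4-D (k,k,Cin,Cout) array");
  k = d[0]; Cin = d[2]; Cout = d[3];
  if (d[1] != k) stop("only square kernels are supported");
  if (Cin != Cin_expected)
    stop("weight input channels (%d) do not match feature channels (%d)", Cin,
         Cin_expected);
}

static NumericVector make_out(int H, int W, int C, int B, bool was3d) {
  NumericVector out((R_xlen_t)H * W * C * B);
  if (was3d)
    out.attr("dim") = IntegerVector::create(H, W, C);
  else
    out.attr("dim") = IntegerVector::create(H, W, C, B);
  return out;
}

// Gather the tap (ki,kj) of a strided/dilated convolution into Xg, whose rows
// are ordered (io fastest, then jo, then b).
static void gather_tap(const double* xp, int H, int W, int C, int B, int Ho,
                       int Wo, int stride, int pad, int dil, int ki, int kj,
                       arma::mat& Xg) {
  const size_t plane = (size_t)H * W;
  const size_t oplane = (size_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    double* col = Xg.colptr(c);
    for (int b = 0; b < B; ++b) {
      const double* xs = xp + plane * (c + (size_t)C * b);
      double* cb = col + oplane * b;
      for (int jo = 0; jo < Wo; ++jo) {
        int jj = jo * stride + kj * dil - pad;
        double* dst = cb + (size_t)jo * Ho;
        if (jj < 0 || jj >= W) {
          std::fill(dst, dst + Ho, 0.0);
          continue;
        }
        const double* xcol = xs + (size_t)jj * H;
        for (int io = 0; io < Ho; ++io) {
          int ii = io * stride + ki * dil - pad;
          dst[io] = (ii >= 0 && ii < H) ? xcol[ii] : 0.0;
        }
      }
    }
  }
}

// Scatter-add the tap matrix M (rows ordered like gather_tap) back into gx.
static void scatter_tap(double* gxp, int H, int W, int C, int B, int Ho, int Wo,
                        int stride, int pad, int dil, int ki, int kj,
                        const arma::mat& M) {
  const size_t plane = (size_t)H * W;
  const size_t oplane = (size_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* col = M.colptr(c);
    for (int b = 0; b < B; ++b) {
      double* xs = gxp + plane * (c + (size_t)C * b);
      const double* cb = col + oplane * b;
      for (int jo = 0; jo < Wo; ++jo) {
        int jj = jo * stride + kj * dil - pad;
        if (jj < 0 || jj >= W) continue;
        double* xcol = xs + (size_t)jj * H;
        const double* src = cb + (size_t)jo * Ho;
        for (int io = 0; io < Ho; ++io) {
          int ii = io * stride + ki * dil - pad;
          if (ii >= 0 && ii < H) xcol[ii] += src[io];
        }
      }
    }
  }
}

static arma::mat tap_weights(const double* wp, int k, int Cin, int Cout, int ki,
                             int kj) {
  arma::mat Wt(Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      Wt(ci, co) = wp[ki + (size_t)k * (kj + (size_t)k * (ci + (size_t)Cin * co))];
  return Wt;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w,
                         Nullable<NumericVector> bias, int stride, int pad,
                         int dil) {
  int H, W, Cin, B; bool was3d;
  get_dims(x, H, W, Cin, B, was3d);
  int k, wci, Cout;
  get_wdims(w, Cin, k, wci, Cout);
  int span = dil * (k - 1) + 1;
  int Ho = (H + 2 * pad - span) / stride + 1;
  int Wo = (W + 2 * pad - span) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");
  int R = B * Ho * Wo;
  arma::mat Y(R, Cout, arma::fill::zeros);
  arma::mat Xg(R, Cin);
  const double* xp = x.begin();
  const double* wp = w.begin();
  for (int ki = 0; ki < k; ++ki)
    for (int kj = 0; kj < k; ++kj) {
      gather_tap(xp, H, W, Cin, B, Ho, Wo, stride, pad, dil, ki, kj, Xg);
      Y += Xg * tap_weights(wp, k, Cin, Cout, ki, kj);
    }
  if (bias.isNotNull()) {
    NumericVector bb(bias);
    if (bb.size() != Cout) stop("bias length does not match output channels");
    for (int co = 0; co < Cout; ++co) Y.col(co) += bb[co];
  }
  NumericVector out = make_out(Ho, Wo, Cout, B, was3d);
  double* op = out.begin();
  const size_t oplane = (size_t)Ho * Wo;
  for (int co = 0; co < Cout; ++co)
    for (int b = 0; b < B; ++b)
      std::copy(Y.colptr(co) + oplane * b, Y.colptr(co) + oplane * (b + 1),
                op + oplane * (co + (size_t)Cout * b));
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad, int dil) {
  int H, W, Cin, B; bool was3d;
  get_dims(x, H, W, Cin, B, was3d);
  int k, wci, Cout;
  get_wdims(w, Cin, k, wci, Cout);
  int Ho, Wo, Cgy, Bgy; bool g3;
  get_dims(gy, Ho, Wo, Cgy, Bgy, g3);
  if (Cgy != Cout || Bgy != B) stop("gradient shape does not match layer");
  int R = B * Ho * Wo;
  // gy as matrix with rows (io, jo, b)
  arma::mat Gy(R, Cout);
  {
    const double* gp = gy.begin();
    const size_t oplane = (size_t)Ho * Wo;
    for (int co = 0; co < Cout; ++co)
      for (int b = 0; b < B; ++b)
        std::copy(gp + oplane * (co + (size_t)Cout * b),
                  gp + oplane * (co + (size_t)Cout * b) + oplane,
                  Gy.colptr(co) + oplane * b);
  }
  NumericVector gx = make_out(H, W, Cin, B, was3d);
  NumericVector gw((R_xlen_t)k * k * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  NumericVector gb(Cout);
  for (int co = 0; co < Cout; ++co) gb[co] = arma::accu(Gy.col(co));
  arma::mat Xg(R, Cin);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* gwp = gw.begin();
  for (int ki = 0; ki < k; ++ki)
    for (int kj = 0; kj < k; ++kj) {
      gather_tap(xp, H, W, Cin, B, Ho, Wo, stride, pad, dil, ki, kj, Xg);
      arma::mat Gw = Xg.t() * Gy;  // Cin x Cout
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          gwp[ki + (size_t)k * (kj + (size_t)k * (ci + (size_t)Cin * co))] =
              Gw(ci, co);
      arma::mat Gxm = Gy * tap_weights(wp, k, Cin, Cout, ki, kj).t();
      scatter_tap(gx.begin(), H, W, Cin, B, Ho, Wo, stride, pad, dil, ki, kj,
                  Gxm);
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution (deconvolution).  Weights (k,k,Cin,Cout) map Cin
// input channels to Cout output channels; output size (H-1)*stride + k - 2*pad.
// [[Rcpp::export]]
NumericVector cpp_deconv2d(NumericVector x, NumericVector w,
                           Nullable<NumericVector> bias, int stride, int pad) {
  int H, W, Cin, B; bool was3d;
  get_dims(x, H, W, Cin, B, was3d);
  int k, wci, Cout;
  get_wdims(w, Cin, k, wci, Cout);
  int Ho = (H - 1) * stride + k - 2 * pad;
  int Wo = (W - 1) * stride + k - 2 * pad;
  if (Ho < 1 || Wo < 1) stop("deconvolution output would be empty");
  int R = B * H * W;
  arma::mat Xm(R, Cin);
  {
    const double* xp = x.begin();
    const size_t plane = (size_t)H * W;
    for (int c = 0; c < Cin; ++c)
      for (int b = 0; b < B; ++b)
        std::copy(xp + plane * (c + (size_t)Cin * b),
                  xp + plane * (c + (size_t)Cin * b) + plane,
                  Xm.colptr(c) + plane * b);
  }
  NumericVector out = make_out(Ho, Wo, Cout, B, was3d);
  double* op = out.begin();
  const double* wp = w.begin();
  const size_t oplane = (size_t)Ho * Wo;
  for (int ki = 0; ki < k; ++ki)
    for (int kj = 0; kj < k; ++kj) {
      arma::mat M = Xm * tap_weights(wp, k, Cin, Cout, ki, kj);  // R x Cout
      for (int co = 0; co < Cout; ++co) {
        const double* col = M.colptr(co);
        for (int b = 0; b < B; ++b) {
          double* ys = op + oplane * (co + (size_t)Cout * b);
          const double* cb = col + (size_t)H * W * b;
          for (int j = 0; j < W; ++j) {
            int oj = j * stride + kj - pad;
            if (oj < 0 || oj >= Wo) continue;
            double* ycol = ys + (size_t)oj * Ho;
            const double* src = cb + (size_t)j * H;
            for (int i = 0; i < H; ++i) {
              int oi = i * stride + ki - pad;
              if (oi >= 0 && oi < Ho) ycol[oi] += src[i];
            }
          }
        }
      }
    }
  if (bias.isNotNull()) {
    NumericVector bb(bias);
    if (bb.size() != Cout) stop("bias length does not match output channels");
    for (int co = 0; co < Cout; ++co)
      for (int b = 0; b < B; ++b) {
        double* ys = op + oplane * (co + (size_t)Cout * b);
        for (size_t t = 0; t < oplane; ++t) ys[t] += bb[co];
      }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_deconv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                      int stride, int pad) {
  int H, W, Cin, B; bool was3d;
  get_dims(x, H, W, Cin, B, was3d);
  int k, wci, Cout;
  get_wdims(w, Cin, k, wci, Cout);
  int Ho, Wo, Cgy, Bgy; bool g3;
  get_dims(gy, Ho, Wo, Cgy, Bgy, g3);
  if (Cgy != Cout || Bgy != B) stop("gradient shape does not match layer");
  int R = B * H * W;
  arma::mat Xm(R, Cin);
  {
    const double* xp = x.begin();
    const size_t plane = (size_t)H * W;
    for (int c = 0; c < Cin; ++c)
      for (int b = 0; b < B; ++b)
        std::copy(xp + plane * (c + (size_t)Cin * b),
                  xp + plane * (c + (size_t)Cin * b) + plane,
                  Xm.colptr(c) + plane * b);
  }
  arma::mat Gxm(R, Cin, arma::fill::zeros);
  NumericVector gw((R_xlen_t)k * k * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  NumericVector gb(Cout);
  {
    const double* gp = gy.begin();
    const size_t oplane = (size_t)Ho * Wo;
    for (int co = 0; co < Cout; ++co) {
      double s = 0;
      for (int b = 0; b < B; ++b) {
        const double* ys = gp + oplane * (co + (size_t)Cout * b);
        for (size_t t = 0; t < oplane; ++t) s += ys[t];
      }
      gb[co] = s;
    }
  }
  arma::mat Gg(R, Cout);
  const double* gp = gy.begin();
  const double* wp = w.begin();
  double* gwp = gw.begin();
  const size_t oplane = (size_t)Ho * Wo;
  for (int ki = 0; ki < k; ++ki)
    for (int kj = 0; kj < k; ++kj) {
      // gather gy at the scatter locations of this tap
      for (int co = 0; co < Cout; ++co) {
        double* col = Gg.colptr(co);
        for (int b = 0; b < B; ++b) {
          const double* ys = gp + oplane * (co + (size_t)Cout * b);
          double* cb = col + (size_t)H * W * b;
          for (int j = 0; j < W; ++j) {
            int oj = j * stride + kj - pad;
            double* dst = cb + (size_t)j * H;
            if (oj < 0 || oj >= Wo) {
              std::fill(dst, dst + H, 0.0);
              continue;
            }
            const double* ycol = ys + (size_t)oj * Ho;
            for (int i = 0; i < H; ++i) {
              int oi = i * stride + ki - pad;
              dst[i] = (oi >= 0 && oi < Ho) ? ycol[oi] : 0.0;
            }
          }
        }
      }
      arma::mat Wt = tap_weights(wp, k, Cin, Cout, ki, kj);
      Gxm += Gg * Wt.t();
      arma::mat Gw = Xm.t() * Gg;  // Cin x Cout
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          gwp[ki + (size_t)k * (kj + (size_t)k * (ci + (size_t)Cin * co))] =
              Gw(ci, co);
    }
  NumericVector gx = make_out(H, W, Cin, B, was3d);
  {
    double* xp = gx.begin();
    const size_t plane = (size_t)H * W;
    for (int c = 0; c < Cin; ++c)
      for (int b = 0; b < B; ++b)
        std::copy(Gxm.colptr(c) + plane * b, Gxm.colptr(c) + plane * (b + 1),
                  xp + plane * (c + (size_t)Cin * b));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
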