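// Fast kernels for the small convolutional hierarchy.  Convolutions are
// 3x3, stride 1, zero-padded ("same"); activations are (h, w, c, n)
// arrays; conv weights are (cout, 9*cin) matrices.  A pure-R reference
// implementation of the same kernels lives in R/conv-ops.R and serves as
// the oracle in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline IntegerVector dims4(const NumericVector &x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  return d;
}

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Gather 3x3 patches of one image into columns of P (9*cin x h*w),
// matching the (dy, dx, ch) row ordering of the R reference.
static void im2col_img(const double *x, int h, int w, int cin, double *p) {
  const int hw = h * w;
  for (int ox = 0; ox < w; ++ox) {
    for (int oy = 0; oy < h; ++oy) {
      double *col = p + (std::size_t)(ox * h + oy) * 9 * cin;
      for (int ch = 0; ch < cin; ++ch) {
        const double *xc = x + (std::size_t)ch * hw;
        for (int dx = -1; dx <= 1; ++dx) {
          const int sx = ox + dx;
          for (int dy = -1; dy <= 1; ++dy) {
            const int sy = oy + dy;
            *col++ = (sy >= 0 && sy < h && sx >= 0 && sx < w)
              ? xc[(std::size_t)sx * h + sy] : 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv3x3_forward")]]
List cpp_conv3x3_forward(NumericVector x, NumericMatrix wmat,
                         NumericVector bias) {
  IntegerVector d = dims4(x);
  const int h = d[0], w = d[1], cin = d[2], n = d[3];
  const int cout = wmat.nrow();
  if (wmat.ncol() != 9 * cin) stop("weight/input channel mismatch");
  const int hw = h * w;

  NumericVector patches((R_xlen_t)9 * cin * hw * n);
  patches.attr("dim") = IntegerVector::create(9 * cin, hw * n);
  for (int i = 0; i < n; ++i) {
    im2col_img(&x[0] + (std::size_t)i * hw * cin, h, w, cin,
               &patches[0] + (std::size_t)i * hw * 9 * cin);
  }
  arma::mat P(&patches[0], 9 * cin, (std::size_t)hw * n, false, true);
  arma::mat W(&wmat[0], cout, 9 * cin, false, true);
  arma::mat Y = W * P;                       // cout x (hw*n)
  Y.each_col() += arma::vec(&bias[0], cout);

  NumericVector out = alloc4(h, w, cout, n);
  double *o = &out[0];
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < cout; ++c) {
      for (int px = 0; px < hw; ++px) {
        o[((std::size_t)i * cout + c) * hw + px] =
          Y(c, (std::size_t)i * hw + px);
      }
    }
  }
  return List::create(_["out"] = out, _["patches"] = patches);
}

// [[Rcpp::export(name = ".cpp_conv3x3_backward")]]
List cpp_conv3x3_backward(NumericVector dout, NumericMatrix wmat,
                          NumericVector patches, int cin) {
  IntegerVector d = dims4(dout);
  const int h = d[0], w = d[1], cout = d[2], n = d[3];
  const int hw = h * w;

  // rearrange dout (h, w, cout, n) -> dY (cout, hw*n)
  arma::mat dY(cout, (std::size_t)hw * n);
  const double *dp = &dout[0];
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < cout; ++c) {
      for (int px = 0; px < hw; ++px) {
        dY(c, (std::size_t)i * hw + px) =
          dp[((std::size_t)i * cout + c) * hw + px];
      }
    }
  }
  arma::mat P(const_cast<double *>(&patches[0]), 9 * cin,
              (std::size_t)hw * n, false, true);
  arma::mat W(&wmat[0], cout, 9 * cin, false, true);
  arma::mat dW = dY * P.t();
  arma::vec db = arma::sum(dY, 1);
  arma::mat dP = W.t() * dY;                 // 9*cin x (hw*n)

  NumericVector dx = alloc4(h, w, cin, n);
  double *dxp = &dx[0];
  for (int i = 0; i < n; ++i) {
    for (int ox = 0; ox < w; ++ox) {
      for (int oy = 0; oy < h; ++oy) {
        const double *col = dP.colptr((std::size_t)i * hw + ox * h + oy);
        for (int ch = 0; ch < cin; ++ch) {
          double *xc = dxp + ((std::size_t)i * cin + ch) * hw;
          for (int dxo = -1; dxo <= 1; ++dxo) {
            const int sx = ox + dxo;
            for (int dyo = -1; dyo <= 1; ++dyo) {
              const int sy = oy + dyo;
              const double v = *col++;
              if (sy >= 0 && sy < h && sx >= 0 && sx < w) {
                xc[(std::size_t)sx * h + sy] += v;
              }
            }
          }
        }
      }
    }
  }
  return List::create(
    _["dx"] = dx,
    _["dw"] = NumericMatrix(cout, 9 * cin, dW.memptr()),
    _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".cpp_relu_forward")]]
NumericVector cpp_relu_forward(NumericVector x) {
  NumericVector out(clone(x));
  for (R_xlen_t i = 0; i < out.size(); ++i) if (out[i] < 0) out[i] = 0;
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export(name = ".cpp_relu_backward")]]
NumericVector cpp_relu_backward(NumericVector dout, NumericVector x) {
  NumericVector dx(dout.size());
  for (R_xlen_t i = 0; i < dx.size(); ++i) dx[i] = x[i] > 0 ? dout[i] : 0;
  dx.attr("dim") = dout.attr("dim");
  return dx;
}

// [[Rcpp::export(name = ".cpp_avgpool2_forward")]]
NumericVector cpp_avgpool2_forward(NumericVector x) {
  IntegerVector d = dims4(x);
  const int h = d[0], w = d[1], c = d[2], n = d[3];
  const int oh = h / 2, ow = w / 2;
  NumericVector out = alloc4(oh, ow, c, n);
  const double *xp = &x[0];
  double *op = &out[0];
  for (std::size_t s = 0; s < (std::size_t)c * n; ++s) {
    const double *xs = xp + s * h * w;
    double *os = op + s * oh * ow;
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        const int sy = 2 * oy, sx = 2 * ox;
        os[(std::size_t)ox * oh + oy] = 0.25 *
          (xs[(std::size_t)sx * h + sy] + xs[(std::size_t)sx * h + sy + 1] +
           xs[(std::size_t)(sx + 1) * h + sy] +
           xs[(std::size_t)(sx + 1) * h + sy + 1]);
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_avgpool2_backward")]]
NumericVector cpp_avgpool2_backward(NumericVector dout, int h, int w) {
  IntegerVector d = dims4(dout);
  const int oh = d[0], ow = d[1], c = d[2], n = d[3];
  NumericVector dx = alloc4(h, w, c, n);
  const double *dp = &dout[0];
  double *xp = &dx[0];
  for (std::size_t s = 0; s < (std::size_t)c * n; ++s) {
    const double *ds = dp + s * oh * ow;
    double *xs = xp + s * h * w;
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        const double g = 0.25 * ds[(std::size_t)ox * oh + oy];
        const int sy = 2 * oy, sx = 2 * ox;
        xs[(std::size_t)sx * h + sy] = g;
        xs[(std::size_t)sx * h + sy + 1] = g;
        xs[(std::size_t)(sx + 1) * h + sy] = g;
        xs[(std::size_t)(sx + 1) * h + sy + 1] = g;
      }
    }
  }
  return dx;
}
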