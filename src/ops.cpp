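// Compiled tensor primitives. All feature maps are R arrays with
// dim = c(H, W, C, N) (column-major, sample-last); convolution weights are
// k x k x Cin x Cout; "same" zero padding so spatial size is preserved.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void getDim4(const NumericVector &x, int &H, int &W, int &C, int &N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Pack weights (k,k,Cin,Cout) into a Cout x (k*k*Cin) matrix whose column
// ordering matches the im2col row ordering below.
static arma::mat weightMatrix(const NumericVector &w, int k, int Cin, int Cout) {
  arma::mat Wm(Cout, (size_t)k * k * Cin);
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < k; ++j)
        for (int i = 0; i < k; ++i)
          Wm(o, i + k * j + (size_t)k * k * c) =
            w[i + (size_t)k * (j + (size_t)k * (c + (size_t)Cin * o))];
  return Wm;
}

// im2col for one sample with dilation; zero padding keeps H x W output.
static void im2col(const double *xn, int H, int W, int Cin, int k, int dil,
                   arma::mat &col) {
  col.zeros();
  const int half = (k - 1) / 2;
  for (int c = 0; c < Cin; ++c) {
    const double *xc = xn + (size_t)c * H * W;
    for (int j = 0; j < k; ++j) {
      const int dj = (j - half) * dil;
      for (int i = 0; i < k; ++i) {
        const int di = (i - half) * dil;
        const size_t r = i + (size_t)k * j + (size_t)k * k * c;
        for (int w2 = 0; w2 < W; ++w2) {
          const int sw = w2 + dj;
          if (sw < 0 || sw >= W) continue;
          for (int h2 = 0; h2 < H; ++h2) {
            const int sh = h2 + di;
            if (sh < 0 || sh >= H) continue;
            col(r, h2 + (size_t)H * w2) = xc[sh + (size_t)H * sw];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2dForwardCpp(NumericVector x, NumericVector w,
                               NumericVector b, int dilation) {
  int H, W, C, N; getDim4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const size_t HW = (size_t)H * W, K = (size_t)k * k * Cin;
  arma::mat Wm = weightMatrix(w, k, Cin, Cout);
  NumericVector y((size_t)HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat col(K, HW);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int n = 0; n < N; ++n) {
    im2col(xp + (size_t)n * C * HW, H, W, Cin, k, dilation, col);
    arma::mat Y = Wm * col;  // Cout x HW
    for (int o = 0; o < Cout; ++o) {
      double *yo = yp + ((size_t)n * Cout + o) * HW;
      const double bo = b[o];
      for (size_t p = 0; p < HW; ++p) yo[p] = Y(o, p) + bo;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2dBackwardCpp(NumericVector x, NumericVector w, NumericVector dy,
                       int dilation) {
  int H, W, C, N; getDim4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  const size_t HW = (size_t)H * W, K = (size_t)k * k * Cin;
  const int half = (k - 1) / 2;
  arma::mat Wm = weightMatrix(w, k, Cin, Cout);

  NumericVector dx((size_t)HW * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat dWm(Cout, K, arma::fill::zeros);
  NumericVector db(Cout);

  arma::mat col(K, HW), dyMat(Cout, HW);
  const double *xp = x.begin(), *dyp = dy.begin();
  double *dxp = dx.begin();

  for (int n = 0; n < N; ++n) {
    im2col(xp + (size_t)n * C * HW, H, W, Cin, k, dilation, col);
    for (int o = 0; o < Cout; ++o) {
      const double *dyo = dyp + ((size_t)n * Cout + o) * HW;
      double s = 0.0;
      for (size_t p = 0; p < HW; ++p) { dyMat(o, p) = dyo[p]; s += dyo[p]; }
      db[o] += s;
    }
    dWm += dyMat * col.t();
    arma::mat colGrad = Wm.t() * dyMat;  // K x HW
    // col2im scatter-add
    for (int c = 0; c < Cin; ++c) {
      double *dxc = dxp + ((size_t)n * C + c) * HW;
      for (int j = 0; j < k; ++j) {
        const int dj = (j - half) * dilation;
        for (int i = 0; i < k; ++i) {
          const int di = (i - half) * dilation;
          const size_t r = i + (size_t)k * j + (size_t)k * k * c;
          for (int w2 = 0; w2 < W; ++w2) {
            const int sw = w2 + dj;
            if (sw < 0 || sw >= W) continue;
            for (int h2 = 0; h2 < H; ++h2) {
              const int sh = h2 + di;
              if (sh < 0 || sh >= H) continue;
              dxc[sh + (size_t)H * sw] += colGrad(r, h2 + (size_t)H * w2);
            }
          }
        }
      }
    }
  }

  NumericVector dw((size_t)k * k * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < k; ++j)
        for (int i = 0; i < k; ++i)
          dw[i + (size_t)k * (j + (size_t)k * (c + (size_t)Cin * o))] =
            dWm(o, i + k * j + (size_t)k * k * c);
  return List::create(_["dx"] = dx, _["dW"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; H and W must be even. Returns pooled map and the
// within-window argmax (0..3, encoded i + 2*j) for the backward pass.
// [[Rcpp::export]]
List maxpool2ForwardCpp(NumericVector x) {
  int H, W, C, N; getDim4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2: H and W must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *xp = x.begin();
  double *yp = y.begin(); int *ip = idx.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double *xc = xp + cn * H * W;
    double *yc = yp + cn * Ho * Wo;
    int *ic = ip + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -1e300; int bi = 0;
        for (int j = 0; j < 2; ++j)
          for (int i = 0; i < 2; ++i) {
            const double v = xc[(2 * ho + i) + (size_t)H * (2 * wo + j)];
            if (v > best) { best = v; bi = i + 2 * j; }
          }
        yc[ho + (size_t)Ho * wo] = best;
        ic[ho + (size_t)Ho * wo] = bi;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2BackwardCpp(NumericVector dy, IntegerVector idx,
                                  int H, int W) {
  int Ho, Wo, C, N; getDim4(dy, Ho, Wo, C, N);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *dyp = dy.begin(); const int *ip = idx.begin();
  double *dxp = dx.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double *dyc = dyp + cn * Ho * Wo;
    const int *ic = ip + cn * Ho * Wo;
    double *dxc = dxp + cn * H * W;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const int b = ic[ho + (size_t)Ho * wo];
        dxc[(2 * ho + b % 2) + (size_t)H * (2 * wo + b / 2)] +=
          dyc[ho + (size_t)Ho * wo];
      }
  }
  return dx;
}

// Transposed convolution, kernel 2x2, stride 2 (spatial size doubles).
// Weights: 2 x 2 x Cin x Cout.
// [[Rcpp::export]]
NumericVector upconv2ForwardCpp(NumericVector x, NumericVector w,
                                NumericVector b) {
  int H, W, C, N; getDim4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("upconv2: channel mismatch");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const double *xp = x.begin(), *wp = w.begin();
  double *yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      double *yo = yp + ((size_t)n * Cout + o) * Ho * Wo;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) yo[p] = b[o];
      for (int c = 0; c < Cin; ++c) {
        const double *xc = xp + ((size_t)n * C + c) * H * W;
        const double *wc = wp + 4 * ((size_t)c + (size_t)Cin * o);
        for (int w2 = 0; w2 < W; ++w2)
          for (int h2 = 0; h2 < H; ++h2) {
            const double v = xc[h2 + (size_t)H * w2];
            for (int j = 0; j < 2; ++j)
              for (int i = 0; i < 2; ++i)
                yo[(2 * h2 + i) + (size_t)Ho * (2 * w2 + j)] += v * wc[i + 2 * j];
          }
      }
    }
  return y;
}

// [[Rcpp::export]]
List upconv2BackwardCpp(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, C, N; getDim4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int Cin = wd[2], Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw(4 * (size_t)Cin * Cout);
  dw.attr("dim") = IntegerVector::create(2, 2, Cin, Cout);
  NumericVector db(Cout);
  const double *xp = x.begin(), *wp = w.begin(), *dyp = dy.begin();
  double *dxp = dx.begin(), *dwp = dw.begin();
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      const double *dyo = dyp + ((size_t)n * Cout + o) * Ho * Wo;
      double s = 0.0;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) s += dyo[p];
      db[o] += s;
      for (int c = 0; c < Cin; ++c) {
        const double *xc = xp + ((size_t)n * C + c) * H * W;
        const double *wc = wp + 4 * ((size_t)c + (size_t)Cin * o);
        double *dxc = dxp + ((size_t)n * C + c) * H * W;
        double *dwc = dwp + 4 * ((size_t)c + (size_t)Cin * o);
        for (int w2 = 0; w2 < W; ++w2)
          for (int h2 = 0; h2 < H; ++h2) {
            double acc = 0.0;
            const double v = xc[h2 + (size_t)H * w2];
            for (int j = 0; j < 2; ++j)
              for (int i = 0; i < 2; ++i) {
                const double g = dyo[(2 * h2 + i) + (size_t)Ho * (2 * w2 + j)];
                acc += g * wc[i + 2 * j];
                dwc[i + 2 * j] += g * v;
              }
            dxc[h2 + (size_t)H * w2] += acc;
          }
      }
    }
  return List::create(_["dx"] = dx, _["dW"] = dw, _["db"] = db);
}
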