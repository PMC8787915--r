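// Low-level numerical kernels: 3D (depthwise) convolution forward/backward
// and dynamic time warping. Arrays are column-major with dims
// (D, H, W, C, N) for activations and (k, k, k, Cin, Cout) for full kernels.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Gather one sample into an im2col matrix (K x M), K = k^3 * C,
// M = Do*Ho*Wo. Row order: kd + k*kh + k^2*kw + k^3*c, matching the
// column-major flattening of the kernel's first four dimensions.
static void im2col(const double* x, int D, int H, int W, int C,
                   int k, int s, int p, int Do, int Ho, int Wo,
                   arma::mat& col) {
  const int K = k * k * k * C;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * D * H * W;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          int r = kd + k * (kh + k * (kw + k * c));
          for (int ow = 0; ow < Wo; ++ow) {
            int iw = ow * s - p + kw;
            if (iw < 0 || iw >= W) continue;
            for (int oh = 0; oh < Ho; ++oh) {
              int ih = oh * s - p + kh;
              if (ih < 0 || ih >= H) continue;
              for (int od = 0; od < Do; ++od) {
                int id = od * s - p + kd;
                if (id < 0 || id >= D) continue;
                int m = od + Do * (oh + Ho * ow);
                col.at(r, m) = xc[id + (size_t)D * (ih + (size_t)H * iw)];
              }
            }
          }
        }
  }
  (void)K;
}

// Scatter-add an im2col-shaped gradient back onto the input sample.
static void col2im(const arma::mat& col, int D, int H, int W, int C,
                   int k, int s, int p, int Do, int Ho, int Wo,
                   double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * D * H * W;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          int r = kd + k * (kh + k * (kw + k * c));
          for (int ow = 0; ow < Wo; ++ow) {
            int iw = ow * s - p + kw;
            if (iw < 0 || iw >= W) continue;
            for (int oh = 0; oh < Ho; ++oh) {
              int ih = oh * s - p + kh;
              if (ih < 0 || ih >= H) continue;
              for (int od = 0; od < Do; ++od) {
                int id = od * s - p + kd;
                if (id < 0 || id >= D) continue;
                int m = od + Do * (oh + Ho * ow);
                xc[id + (size_t)D * (ih + (size_t)H * iw)] += col.at(r, m);
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  int k = wd[0], Cout = wd[4];
  if (wd[3] != C) stop("kernel input channels do not match input");
  int Do = out_size(D, k, stride, pad);
  int Ho = out_size(H, k, stride, pad);
  int Wo = out_size(W, k, stride, pad);
  if (Do < 1 || Ho < 1 || Wo < 1) stop("convolution output would be empty");
  int K = k * k * k * C, M = Do * Ho * Wo;

  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector y((size_t)M * Cout * N);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout, N);
  arma::mat col(K, M);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * D * H * W * C, D, H, W, C,
           k, stride, pad, Do, Ho, Wo, col);
    arma::mat Yt(y.begin() + (size_t)n * M * Cout, M, Cout, false, true);
    Yt = col.t() * Wm;
    for (int f = 0; f < Cout; ++f) Yt.col(f) += b[f];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  int k = wd[0], Cout = wd[4];
  int Do = yd[0], Ho = yd[1], Wo = yd[2];
  int K = k * k * k * C, M = Do * Ho * Wo;

  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector dx((size_t)D * H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)K * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat col(K, M);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * D * H * W * C, D, H, W, C,
           k, stride, pad, Do, Ho, Wo, col);
    arma::mat Dm(dy.begin() + (size_t)n * M * Cout, M, Cout, false, true);
    dWm += col * Dm;
    dbv += arma::sum(Dm, 0).t();
    arma::mat dcol = Wm * Dm.t();
    col2im(dcol, D, H, W, C, k, stride, pad, Do, Ho, Wo,
           dx.begin() + (size_t)n * D * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Depthwise convolution: one k^3 kernel per channel, w dims (k, k, k, C).
// [[Rcpp::export]]
NumericVector cpp_dwconv3d_fwd(NumericVector x, NumericVector w,
                               int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  int k = wd[0];
  if (wd[3] != C) stop("depthwise kernel channels do not match input");
  int Do = out_size(D, k, stride, pad);
  int Ho = out_size(H, k, stride, pad);
  int Wo = out_size(W, k, stride, pad);
  if (Do < 1 || Ho < 1 || Wo < 1) stop("convolution output would be empty");

  NumericVector y((size_t)Do * Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Do, Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(n * C + c) * D * H * W;
      const double* wc = w.begin() + (size_t)c * k * k * k;
      double* yc = y.begin() + (size_t)(n * C + c) * Do * Ho * Wo;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh)
          for (int od = 0; od < Do; ++od) {
            double acc = 0.0;
            for (int kw = 0; kw < k; ++kw) {
              int iw = ow * stride - pad + kw;
              if (iw < 0 || iw >= W) continue;
              for (int kh = 0; kh < k; ++kh) {
                int ih = oh * stride - pad + kh;
                if (ih < 0 || ih >= H) continue;
                for (int kd = 0; kd < k; ++kd) {
                  int id = od * stride - pad + kd;
                  if (id < 0 || id >= D) continue;
                  acc += xc[id + (size_t)D * (ih + (size_t)H * iw)] *
                         wc[kd + k * (kh + k * kw)];
                }
              }
            }
            yc[od + (size_t)Do * (oh + (size_t)Ho * ow)] = acc;
          }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv3d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                      int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = dy.attr("dim");
  int D = xd[0], H = xd[1], W = xd[2], C = xd[3], N = xd[4];
  int k = wd[0];
  int Do = yd[0], Ho = yd[1], Wo = yd[2];

  NumericVector dx((size_t)D * H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)k * k * k * C);
  dw.attr("dim") = wd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(n * C + c) * D * H * W;
      const double* dyc = dy.begin() + (size_t)(n * C + c) * Do * Ho * Wo;
      double* dxc = dx.begin() + (size_t)(n * C + c) * D * H * W;
      double* dwc = dw.begin() + (size_t)c * k * k * k;
      const double* wc = w.begin() + (size_t)c * k * k * k;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh)
          for (int od = 0; od < Do; ++od) {
            double g = dyc[od + (size_t)Do * (oh + (size_t)Ho * ow)];
            if (g == 0.0) continue;
            for (int kw = 0; kw < k; ++kw) {
              int iw = ow * stride - pad + kw;
              if (iw < 0 || iw >= W) continue;
              for (int kh = 0; kh < k; ++kh) {
                int ih = oh * stride - pad + kh;
                if (ih < 0 || ih >= H) continue;
                for (int kd = 0; kd < k; ++kd) {
                  int id = od * stride - pad + kd;
                  if (id < 0 || id >= D) continue;
                  size_t xi = id + (size_t)D * (ih + (size_t)H * iw);
                  dwc[kd + k * (kh + k * kw)] += g * xc[xi];
                  dxc[xi] += g * wc[kd + k * (kh + k * kw)];
                }
              }
            }
          }
    }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Classic DTW dynamic program: local cost |a_i - b_j|, steps
// {(1,0),(0,1),(1,1)}, no warping window, unnormalised global alignment.
// [[Rcpp::export]]
double cpp_dtw(NumericVector a, NumericVector b) {
  int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      double cost = std::fabs(a[i - 1] - b[j - 1]);
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
NumericMatrix cpp_pairwise_dtw(NumericMatrix x) {
  int n = x.nrow();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    NumericVector a = x(i, _);
    for (int j = i + 1; j < n; ++j) {
      double v = cpp_dtw(a, x(j, _));
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  return d;
}
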