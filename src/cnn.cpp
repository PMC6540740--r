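// Convolution and pooling primitives for the label classifier.
//
// Feature maps are R arrays [H, W, C, B] (column-major). 3x3 convolutions
// use same-padding and are computed as im2col + one GEMM; max pooling is
// 3x3 with stride 2 and SAME padding (output = ceiling(in/2)). The im2col
// matrix is returned to the R side and fed back to the backward pass so it
// is built once per step. im2col rows are spatial positions (h fastest,
// then w, then batch) and columns are (channel, kernel-offset) pairs, so
// every fill and scatter loop below runs down contiguous memory.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void get_dims4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// (H*W*B) x (C*9) im2col of a 3x3 same-padded neighbourhood.
static arma::mat im2col3(const double* x, int H, int W, int C, int B) {
  arma::mat cols((size_t)H * W * B, C * 9, arma::fill::zeros);
  for (int k = 0; k < 9; ++k) {
    int dy = k % 3 - 1, dx = k / 3 - 1;
    for (int c = 0; c < C; ++c) {
      double* dst0 = cols.colptr(c + C * k);
      for (int b = 0; b < B; ++b) {
        const double* xc = x + ((size_t)b * C + c) * H * W;
        for (int w = 0; w < W; ++w) {
          int ws = w + dx;
          if (ws < 0 || ws >= W) continue;
          double* dst = dst0 + (size_t)b * H * W + (size_t)w * H;
          const double* src = xc + (size_t)ws * H;
          int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
          for (int h = h0; h < h1; ++h) dst[h] = src[h + dy];
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".conv3_fwd")]]
List conv3_fwd(NumericVector x, const arma::mat& K, const arma::vec& bias) {
  int d[4];
  get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const int Cout = K.n_rows;
  if ((int)K.n_cols != C * 9) stop("kernel matrix has wrong width");
  arma::mat cols = im2col3(REAL(x), H, W, C, B);
  arma::mat out = cols * K.t();      // (H*W*B) x Cout
  NumericVector y(Rf_allocVector(REALSXP, (size_t)H * W * Cout * B));
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);
  double* yp = REAL(y);
  const size_t plane = (size_t)H * W;
  for (int co = 0; co < Cout; ++co) {
    const double* op = out.colptr(co);
    const double bs = bias[co];
    for (int b = 0; b < B; ++b) {
      double* dst = yp + ((size_t)b * Cout + co) * plane;
      const double* src = op + (size_t)b * plane;
      for (size_t p = 0; p < plane; ++p) dst[p] = src[p] + bs;
    }
  }
  return List::create(_["y"] = y, _["cols"] = cols);
}

// [[Rcpp::export(name = ".conv3_bwd")]]
List conv3_bwd(NumericVector dy, const arma::mat& K, const arma::mat& cols,
               IntegerVector in_dim) {
  IntegerVector dm = dy.attr("dim");
  const int H = dm[0], W = dm[1], Cout = dm[2], B = dm[3];
  const int C = in_dim[2];
  const size_t plane = (size_t)H * W;
  arma::mat dym((size_t)H * W * B, Cout);
  const double* dp = REAL(dy);
  for (int co = 0; co < Cout; ++co) {
    double* dst0 = dym.colptr(co);
    for (int b = 0; b < B; ++b) {
      const double* src = dp + ((size_t)b * Cout + co) * plane;
      double* dst = dst0 + (size_t)b * plane;
      for (size_t p = 0; p < plane; ++p) dst[p] = src[p];
    }
  }
  arma::mat dK = dym.t() * cols;      // Cout x (C*9)
  arma::rowvec db = arma::sum(dym, 0);
  arma::mat dcols = dym * K;          // (H*W*B) x (C*9)
  NumericVector dx(Rf_allocVector(REALSXP, (size_t)H * W * C * B));
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  std::fill(REAL(dx), REAL(dx) + (size_t)H * W * C * B, 0.0);
  double* dxp = REAL(dx);
  for (int k = 0; k < 9; ++k) {
    int dy_ = k % 3 - 1, dx_ = k / 3 - 1;
    for (int c = 0; c < C; ++c) {
      const double* src0 = dcols.colptr(c + C * k);
      for (int b = 0; b < B; ++b) {
        double* dc = dxp + ((size_t)b * C + c) * plane;
        for (int w = 0; w < W; ++w) {
          int ws = w + dx_;
          if (ws < 0 || ws >= W) continue;
          const double* src = src0 + (size_t)b * plane + (size_t)w * H;
          double* dst = dc + (size_t)ws * H + dy_;
          int h0 = std::max(0, -dy_), h1 = std::min(H, H - dy_);
          for (int h = h0; h < h1; ++h) dst[h] += src[h];
        }
      }
    }
  }
  return List::create(_["dK"] = dK, _["db"] = db, _["dx"] = dx);
}

// [[Rcpp::export(name = ".pool3s2_fwd")]]
List pool3s2_fwd(NumericVector x) {
  int d[4];
  get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  const int pt = (2 * Ho + 1 - H) / 2, pl = (2 * Wo + 1 - W) / 2;
  const double* xp = REAL(x);
  size_t nout = (size_t)Ho * Wo * C * B;
  NumericVector y(Rf_allocVector(REALSXP, nout));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector am(Rf_allocVector(INTSXP, nout)); // 0-based index into x
  double* yp = REAL(y);
  int* ap = INTEGER(am);
  size_t o = 0;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((size_t)b * C + c) * H * W;
      size_t choff = ((size_t)b * C + c) * (size_t)H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          size_t bi = 0;
          for (int dx = 0; dx < 3; ++dx) {
            int w = 2 * wo + dx - pl;
            if (w < 0 || w >= W) continue;
            for (int dy = 0; dy < 3; ++dy) {
              int h = 2 * ho + dy - pt;
              if (h < 0 || h >= H) continue;
              double v = xc[(size_t)w * H + h];
              if (v > best) { best = v; bi = choff + (size_t)w * H + h; }
            }
          }
          // y is [Ho, Wo, C, B]: for fixed (b, c, wo) consecutive ho are
          // consecutive in memory
          o = (size_t)ho + Ho * ((size_t)wo + Wo * ((size_t)c + (size_t)C * b));
          yp[o] = best;
          ap[o] = (int)bi;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export(name = ".pool3s2_bwd")]]
NumericVector pool3s2_bwd(NumericVector dy, IntegerVector argmax,
                          IntegerVector in_dim) {
  size_t nin = (size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector dx(Rf_allocVector(REALSXP, nin));
  dx.attr("dim") = in_dim;
  std::fill(REAL(dx), REAL(dx) + nin, 0.0);
  double* dxp = REAL(dx);
  const double* dp = REAL(dy);
  const int* ap = INTEGER(argmax);
  size_t n = dy.size();
  for (size_t i = 0; i < n; ++i) dxp[ap[i]] += dp[i];
  return dx;
}
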