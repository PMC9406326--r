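#include <Rcpp.h>
using namespace Rcpp;

// Patch gather for im2col: out(i, j) = x[idx(i, j) - 1].
// idx is the precomputed (rows x K) index matrix of a convolution geometry.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericVector& x, const IntegerMatrix& idx) {
  const int n = idx.nrow(), K = idx.ncol();
  NumericMatrix out(n, K);
  const double* xp = x.begin();
  for (int j = 0; j < K; ++j) {
    const int* ij = &idx(0, j);
    double* oj = &out(0, j);
    for (int i = 0; i < n; ++i) oj[i] = xp[ij[i] - 1];
  }
  return out;
}

// Paired gather for complex im2col: columns 1..K hold the real component
// patches, columns K+1..2K the imaginary ones (one allocation, no cbind).
// [[Rcpp::export]]
NumericMatrix cpp_im2col2(const NumericVector& xre, const NumericVector& xim,
                          const IntegerMatrix& idx) {
  const int n = idx.nrow(), K = idx.ncol();
  NumericMatrix out(n, 2 * K);
  const double* rp = xre.begin();
  const double* ip = xim.begin();
  for (int j = 0; j < K; ++j) {
    const int* ij = &idx(0, j);
    double* oj = &out(0, j);
    double* oj2 = &out(0, K + j);
    for (int i = 0; i < n; ++i) {
      const int t = ij[i] - 1;
      oj[i] = rp[t];
      oj2[i] = ip[t];
    }
  }
  return out;
}

// Scatter-accumulate for the convolution input gradient (col2im):
// dx[idx(i, j) - 1] += dcols(i, j), dx of length n.
// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& dcols, const IntegerMatrix& idx,
                         const int n) {
  NumericVector dx(n);
  const int rows = idx.nrow(), K = idx.ncol();
  double* dp = dx.begin();
  for (int j = 0; j < K; ++j) {
    const int* ij = &idx(0, j);
    const double* cj = &dcols(0, j);
    for (int i = 0; i < rows; ++i) dp[ij[i] - 1] += cj[i];
  }
  return dx;
}

// Paired col2im: dcols holds [real | imaginary] column blocks of width K.
// [[Rcpp::export]]
List cpp_col2im2(const NumericMatrix& dcols, const IntegerMatrix& idx,
                 const int n) {
  NumericVector dre(n), dim_(n);
  const int rows = idx.nrow(), K = idx.ncol();
  double* rp = dre.begin();
  double* ip = dim_.begin();
  for (int j = 0; j < K; ++j) {
    const int* ij = &idx(0, j);
    const double* cr = &dcols(0, j);
    const double* ci = &dcols(0, K + j);
    for (int i = 0; i < rows; ++i) {
      const int t = ij[i] - 1;
      rp[t] += cr[i];
      ip[t] += ci[i];
    }
  }
  return List::create(_["re"] = dre, _["im"] = dim_);
}

// (oh, ow, C, B) array -> (oh*ow*B x C) matrix with rows ordered
// position-fastest then batch, matching the im2col row order.
// [[Rcpp::export]]
NumericMatrix cpp_nhwc_to_mat(const NumericVector& a, const int oh,
                              const int ow, const int C, const int B) {
  const int P = oh * ow;
  NumericMatrix out(P * B, C);
  const double* ap = a.begin();
  for (int o = 0; o < C; ++o) {
    double* op = &out(0, o);
    for (int b = 0; b < B; ++b) {
      const double* src = ap + (size_t)P * (o + (size_t)C * b);
      double* dst = op + (size_t)P * b;
      for (int p = 0; p < P; ++p) dst[p] = src[p];
    }
  }
  return out;
}

// Paired variant: [real | imaginary] column blocks from two arrays.
// [[Rcpp::export]]
NumericMatrix cpp_nhwc_to_mat2(const NumericVector& are,
                               const NumericVector& aim, const int oh,
                               const int ow, const int C, const int B) {
  const int P = oh * ow;
  NumericMatrix out(P * B, 2 * C);
  const double* rp = are.begin();
  const double* ip = aim.begin();
  for (int o = 0; o < C; ++o) {
    double* or_ = &out(0, o);
    double* oi = &out(0, C + o);
    for (int b = 0; b < B; ++b) {
      const size_t s = (size_t)P * (o + (size_t)C * b);
      const size_t d = (size_t)P * b;
      for (int p = 0; p < P; ++p) {
        or_[d + p] = rp[s + p];
        oi[d + p] = ip[s + p];
      }
    }
  }
  return out;
}

// Inverse of cpp_nhwc_to_mat for a column block [off, off + C) of Y.
// [[Rcpp::export]]
NumericVector cpp_mat_to_nhwc(const NumericMatrix& Y, const int oh,
                              const int ow, const int C, const int B,
                              const int off) {
  const int P = oh * ow;
  NumericVector a((R_xlen_t)P * C * B);
  a.attr("dim") = IntegerVector::create(oh, ow, C, B);
  double* ap = a.begin();
  for (int o = 0; o < C; ++o) {
    const double* yp = &Y(0, off + o);
    for (int b = 0; b < B; ++b) {
      const double* src = yp + (size_t)P * b;
      double* dst = ap + (size_t)P * (o + (size_t)C * b);
      for (int p = 0; p < P; ++p) dst[p] = src[p];
    }
  }
  return a;
}
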