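// Batched matrix multiplication kernels for the attention and graph
// convolution blocks. Arrays are column-major with the batch as the FIRST
// dimension, so the inner accumulation loop over the batch index is
// contiguous for all three operands.

#include <Rcpp.h>
using namespace Rcpp;

// A is (M, an, ak), B is (M, bn, bk); computes C(m,,) = op(A)(m,,) %*% op(B)(m,,)
// with op = transpose when ta/tb.
// [[Rcpp::export(name = ".bmm_fwd_cpp")]]
NumericVector bmm_fwd_cpp(NumericVector A, NumericVector B,
                          IntegerVector dA, IntegerVector dB,
                          bool ta, bool tb) {
  const int M = dA[0], an = dA[1], ak = dA[2], bn = dB[1], bk = dB[2];
  const int r = ta ? ak : an, q = ta ? an : ak, c = tb ? bn : bk;
  NumericVector out((R_xlen_t)M * r * c);
  const double* pa = A.begin();
  const double* pb = B.begin();
  double* po = out.begin();
  for (int l = 0; l < q; ++l) {
    for (int i = 0; i < r; ++i) {
      const R_xlen_t ia = ta ? (R_xlen_t)M * (l + (R_xlen_t)an * i)
                             : (R_xlen_t)M * (i + (R_xlen_t)an * l);
      for (int j = 0; j < c; ++j) {
        const R_xlen_t ib = tb ? (R_xlen_t)M * (j + (R_xlen_t)bn * l)
                               : (R_xlen_t)M * (l + (R_xlen_t)bn * j);
        const R_xlen_t io = (R_xlen_t)M * (i + (R_xlen_t)r * j);
        const double* a = pa + ia;
        const double* b = pb + ib;
        double* o = po + io;
        for (int m = 0; m < M; ++m) o[m] += a[m] * b[m];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(M, r, c);
  return out;
}

// Gradients of bmm_fwd_cpp w.r.t. A and/or B given upstream gradient G
// (M, r, c). Writes directly in the raw layouts of A and B.
// [[Rcpp::export(name = ".bmm_bwd_cpp")]]
List bmm_bwd_cpp(NumericVector G, NumericVector A, NumericVector B,
                 IntegerVector dA, IntegerVector dB,
                 bool ta, bool tb, bool need_ga, bool need_gb) {
  const int M = dA[0], an = dA[1], ak = dA[2], bn = dB[1], bk = dB[2];
  const int r = ta ? ak : an, q = ta ? an : ak, c = tb ? bn : bk;
  NumericVector ga(need_ga ? (R_xlen_t)M * an * ak : 0);
  NumericVector gb(need_gb ? (R_xlen_t)M * bn * bk : 0);
  const double* pa = A.begin();
  const double* pb = B.begin();
  const double* pg = G.begin();
  double* pga = ga.begin();
  double* pgb = gb.begin();
  for (int l = 0; l < q; ++l) {
    for (int i = 0; i < r; ++i) {
      const R_xlen_t ia = ta ? (R_xlen_t)M * (l + (R_xlen_t)an * i)
                             : (R_xlen_t)M * (i + (R_xlen_t)an * l);
      for (int j = 0; j < c; ++j) {
        const R_xlen_t ib = tb ? (R_xlen_t)M * (j + (R_xlen_t)bn * l)
                               : (R_xlen_t)M * (l + (R_xlen_t)bn * j);
        const R_xlen_t io = (R_xlen_t)M * (i + (R_xlen_t)r * j);
        const double* g = pg + io;
        if (need_ga) {
          const double* b = pb + ib;
          double* o = pga + ia;
          for (int m = 0; m < M; ++m) o[m] += g[m] * b[m];
        }
        if (need_gb) {
          const double* a = pa + ia;
          double* o = pgb + ib;
          for (int m = 0; m < M; ++m) o[m] += a[m] * g[m];
        }
      }
    }
  }
  if (need_ga) ga.attr("dim") = dA;
  if (need_gb) gb.attr("dim") = dB;
  return List::create(Named("ga") = ga, Named("gb") = gb);
}
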