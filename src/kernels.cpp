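#include <Rcpp.h>
#include <cfloat>
#include <cmath>
#include <complex>
using namespace Rcpp;

// CSR sparse matrix-vector product, double precision.
// row_ptr: length n+1, 0-based offsets; col_ind: 0-based column indices.
// [[Rcpp::export]]
NumericVector csr_matvec_dbl(IntegerVector row_ptr, IntegerVector col_ind,
                             NumericVector vals, NumericVector x) {
  int n = row_ptr.size() - 1;
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k)
      acc += vals[k] * x[col_ind[k]];
    y[i] = acc;
  }
  return y;
}

// CSR mat-vec with all arithmetic carried out in IEEE single precision:
// matrix values and vector entries are cast to float, products and the
// row accumulation are float. This is the arithmetic a single-precision
// solver performs; the result is returned widened to double for storage.
// [[Rcpp::export]]
NumericVector csr_matvec_sgl(IntegerVector row_ptr, IntegerVector col_ind,
                             NumericVector vals, NumericVector x) {
  int n = row_ptr.size() - 1;
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    float acc = 0.0f;
    for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k)
      acc += (float)vals[k] * (float)x[col_ind[k]];
    y[i] = (double)acc;
  }
  return y;
}

// CSR mat-vec, complex double.
// [[Rcpp::export]]
ComplexVector csr_matvec_cplx(IntegerVector row_ptr, IntegerVector col_ind,
                              ComplexVector vals, ComplexVector x) {
  int n = row_ptr.size() - 1;
  ComplexVector y(n);
  for (int i = 0; i < n; ++i) {
    std::complex<double> acc(0.0, 0.0);
    for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k) {
      std::complex<double> v(vals[k].r, vals[k].i);
      std::complex<double> xv(x[col_ind[k]].r, x[col_ind[k]].i);
      acc += v * xv;
    }
    y[i].r = acc.real();
    y[i].i = acc.imag();
  }
  return y;
}

// Accumulate element-local contributions into a CSR value array in the
// order given (element index order). pos is 0-based position of each
// contribution in the value array. When single = true the running sums
// are kept in float, reproducing native single-precision assembly;
// otherwise sums are double.
// [[Rcpp::export]]
NumericVector accumulate_csr(IntegerVector pos, NumericVector contrib,
                             int nnz, bool single) {
  NumericVector out(nnz);
  int m = pos.size();
  if (single) {
    std::vector<float> acc(nnz, 0.0f);
    for (int k = 0; k < m; ++k) acc[pos[k]] += (float)contrib[k];
    for (int k = 0; k < nnz; ++k) out[k] = (double)acc[k];
  } else {
    std::vector<double> acc(nnz, 0.0);
    for (int k = 0; k < m; ++k) acc[pos[k]] += contrib[k];
    for (int k = 0; k < nnz; ++k) out[k] = acc[k];
  }
  return out;
}

// Round each entry to the nearest IEEE single-precision value (kept in a
// double vector). Errors on single-range overflow.
// [[Rcpp::export]]
NumericVector round_to_single(NumericVector x) {
  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    if (std::isfinite(v) && std::fabs(v) > (double)FLT_MAX)
      stop("value %g overflows single-precision range", v);
    y[i] = (double)(float)v;
  }
  return y;
}

// Locate points in a tetrahedral mesh. For each query point returns the
// 0-based index of a containing element (-1 if outside) and the four
// barycentric coordinates w.r.t. that element. Containment test uses a
// small negative tolerance so points on faces are accepted.
// [[Rcpp::export]]
List locate_points_tet(NumericMatrix nodes, IntegerMatrix elems,
                       NumericMatrix pts, double tol) {
  int ne = elems.nrow(), np = pts.nrow();
  IntegerVector elem_of(np);
  NumericMatrix bary(np, 4);

  // Precompute per-element inverse affine maps (3x3 inverse + origin).
  std::vector<double> inv(ne * 9), orig(ne * 3);
  std::vector<bool> ok(ne, true);
  for (int e = 0; e < ne; ++e) {
    int a = elems(e, 0), b = elems(e, 1), c = elems(e, 2), d = elems(e, 3);
    double m[9];
    for (int j = 0; j < 3; ++j) {
      m[0 + j] = nodes(b, j) - nodes(a, j);
      m[3 + j] = nodes(c, j) - nodes(a, j);
      m[6 + j] = nodes(d, j) - nodes(a, j);
      orig[e * 3 + j] = nodes(a, j);
    }
    // columns of m^T are edge vectors; invert the 3x3 with rows = edges
    double det =
        m[0] * (m[4] * m[8] - m[5] * m[7]) -
        m[1] * (m[3] * m[8] - m[5] * m[6]) +
        m[2] * (m[3] * m[7] - m[4] * m[6]);
    if (std::fabs(det) < 1e-300) { ok[e] = false; continue; }
    double *iv = &inv[e * 9];
    // inverse of matrix with rows m[0:2], m[3:5], m[6:8]
    iv[0] = (m[4] * m[8] - m[5] * m[7]) / det;
    iv[1] = (m[2] * m[7] - m[1] * m[8]) / det;
    iv[2] = (m[1] * m[5] - m[2] * m[4]) / det;
    iv[3] = (m[5] * m[6] - m[3] * m[8]) / det;
    iv[4] = (m[0] * m[8] - m[2] * m[6]) / det;
    iv[5] = (m[2] * m[3] - m[0] * m[5]) / det;
    iv[6] = (m[3] * m[7] - m[4] * m[6]) / det;
    iv[7] = (m[1] * m[6] - m[0] * m[7]) / det;
    iv[8] = (m[0] * m[4] - m[1] * m[3]) / det;
  }

  for (int p = 0; p < np; ++p) {
    elem_of[p] = -1;
    double best_min = -1e300;
    int best_e = -1;
    double best_b[4] = {0, 0, 0, 0};
    for (int e = 0; e < ne; ++e) {
      if (!ok[e]) continue;
      double r[3];
      for (int j = 0; j < 3; ++j) r[j] = pts(p, j) - orig[e * 3 + j];
      const double *iv = &inv[e * 9];
      // r = M^T * (l1,l2,l3) with M rows the edge vectors, so
      // (l1,l2,l3) = M^{-T} r: dot r with the columns of M^{-1}
      double l1 = iv[0] * r[0] + iv[3] * r[1] + iv[6] * r[2];
      double l2 = iv[1] * r[0] + iv[4] * r[1] + iv[7] * r[2];
      double l3 = iv[2] * r[0] + iv[5] * r[1] + iv[8] * r[2];
      double l0 = 1.0 - l1 - l2 - l3;
      double mn = std::min(std::min(l0, l1), std::min(l2, l3));
      if (mn >= -tol) {
        elem_of[p] = e;
        bary(p, 0) = l0; bary(p, 1) = l1; bary(p, 2) = l2; bary(p, 3) = l3;
        best_e = -2;  // found
        break;
      }
      if (mn > best_min) {
        best_min = mn; best_e = e;
        best_b[0] = l0; best_b[1] = l1; best_b[2] = l2; best_b[3] = l3;
      }
    }
    if (elem_of[p] < 0 && best_e >= 0 && best_min >= -64 * tol) {
      // near-miss due to round-off at shared faces: accept best candidate
      elem_of[p] = best_e;
      for (int j = 0; j < 4; ++j) bary(p, j) = best_b[j];
    }
  }
  return List::create(_["elem"] = elem_of, _["bary"] = bary);
}
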