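#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction for 3x3x3 convolution with zero padding, stride 1.
// x holds `nsub` stacked subject blocks: (nsub*V) x C, where each block is a
// d1*d2*d3 grid in column-major voxel order (v = i + d1*(j + d2*k)).
// Returns (nsub*V) x (27*C); output column = c*27 + o with offset index
// o = (di+1) + 3*(dj+1) + 9*(dk+1), di/dj/dk in {-1,0,1}. Patches never
// cross subject boundaries.
// [[Rcpp::export]]
NumericMatrix im2col3(NumericMatrix x, IntegerVector dims, int nsub = 1) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int V = d1 * d2 * d3, C = x.ncol();
  const R_xlen_t rows = (R_xlen_t)nsub * V;
  NumericMatrix out(rows, 27 * C);
  for (int s = 0; s < nsub; ++s) {
    const R_xlen_t base = (R_xlen_t)s * V;
    for (int c = 0; c < C; ++c) {
      const double* xc = &x(base, c);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int o = (di + 1) + 3 * (dj + 1) + 9 * (dk + 1);
            double* oc = &out(base, c * 27 + o);
            for (int k = 0; k < d3; ++k) {
              const int kk = k + dk;
              if (kk < 0 || kk >= d3) continue;
              for (int j = 0; j < d2; ++j) {
                const int jj = j + dj;
                if (jj < 0 || jj >= d2) continue;
                const int lo = (di < 0) ? 1 : 0;
                const int hi = (di > 0) ? d1 - 1 : d1;
                const double* src = xc + d1 * (jj + (size_t)d2 * kk) + di;
                double* dst = oc + d1 * (j + (size_t)d2 * k);
                for (int i = lo; i < hi; ++i) dst[i] = src[i];
              }
            }
          }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add a (nsub*V) x (27*C) gradient back to
// (nsub*V) x C.
// [[Rcpp::export]]
NumericMatrix col2im3(NumericMatrix g, IntegerVector dims, int nsub = 1) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int V = d1 * d2 * d3;
  const int C = g.ncol() / 27;
  NumericMatrix out((R_xlen_t)nsub * V, C);
  for (int s = 0; s < nsub; ++s) {
    const R_xlen_t base = (R_xlen_t)s * V;
    for (int c = 0; c < C; ++c) {
      double* oc = &out(base, c);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int o = (di + 1) + 3 * (dj + 1) + 9 * (dk + 1);
            const double* gc = &g(base, c * 27 + o);
            for (int k = 0; k < d3; ++k) {
              const int kk = k + dk;
              if (kk < 0 || kk >= d3) continue;
              for (int j = 0; j < d2; ++j) {
                const int jj = j + dj;
                if (jj < 0 || jj >= d2) continue;
                const int lo = (di < 0) ? 1 : 0;
                const int hi = (di > 0) ? d1 - 1 : d1;
                double* dst = oc + d1 * (jj + (size_t)d2 * kk) + di;
                const double* src = gc + d1 * (j + (size_t)d2 * k);
                for (int i = lo; i < hi; ++i) dst[i] += src[i];
              }
            }
          }
    }
  }
  return out;
}
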