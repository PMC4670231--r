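#include <Rcpp.h>
using namespace Rcpp;

// Sum of x over a fixed set of integer offsets around every pixel.
// Off-lattice neighbours contribute 0 (outside the study region there are
// no particles).  Offsets are 0-based (di = row shift, dj = col shift).
// [[Rcpp::export]]
NumericMatrix disc_sum_filter(const NumericMatrix& x,
                              const IntegerVector& di,
                              const IntegerVector& dj) {
  const int nr = x.nrow(), nc = x.ncol(), m = di.size();
  NumericMatrix out(nr, nc);
  for (int k = 0; k < m; ++k) {
    const int a = di[k], b = dj[k];
    const int i0 = std::max(0, -a), i1 = std::min(nr, nr - a);
    const int j0 = std::max(0, -b), j1 = std::min(nc, nc - b);
    for (int j = j0; j < j1; ++j) {
      const double* src = &x(0, j + b);
      double* dst = &out(0, j);
      for (int i = i0; i < i1; ++i) dst[i] += src[i + a];
    }
  }
  return out;
}

// Same disc sum, evaluated via column prefix sums: the pixelated disc is,
// for each column offset dj, a contiguous run of rows [-hd[k], hd[k]], so the
// sum over the disc is a sum of 2R+1 run sums, each O(1) after an O(N)
// prefix pass.  Off-lattice neighbours contribute 0.
// [[Rcpp::export]]
NumericMatrix disc_sum_filter_runs(const NumericMatrix& x,
                                   const IntegerVector& dj,
                                   const IntegerVector& hd) {
  const int nr = x.nrow(), nc = x.ncol(), m = dj.size();
  NumericMatrix pre(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    double acc = 0.0;
    for (int i = 0; i < nr; ++i) {
      acc += x(i, j);
      pre(i, j) = acc;
    }
  }
  for (int k = 0; k < m; ++k) {
    const int b = dj[k], h = hd[k];
    const int j0 = std::max(0, -b), j1 = std::min(nc, nc - b);
    for (int j = j0; j < j1; ++j) {
      const double* col = &pre(0, j + b);
      double* dst = &out(0, j);
      for (int i = 0; i < nr; ++i) {
        const int top = std::min(i + h, nr - 1);
        const int bot = i - h - 1;
        dst[i] += col[top] - (bot >= 0 ? col[bot] : 0.0);
      }
    }
  }
  return out;
}

// Minimum of x over the offset neighbourhood (grayscale erosion with a flat
// structuring element).  Out-of-lattice neighbours take the value `pad`;
// NA pad means "ignore" (minimum over in-lattice neighbours only).
// [[Rcpp::export]]
NumericMatrix disc_min_filter(const NumericMatrix& x,
                              const IntegerVector& di,
                              const IntegerVector& dj,
                              double pad) {
  const int nr = x.nrow(), nc = x.ncol(), m = di.size();
  const bool ignore = NumericVector::is_na(pad);
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int k = 0; k < m; ++k) {
    const int a = di[k], b = dj[k];
    for (int j = 0; j < nc; ++j) {
      const int jj = j + b;
      const bool jin = (jj >= 0 && jj < nc);
      for (int i = 0; i < nr; ++i) {
        const int ii = i + a;
        double v;
        if (jin && ii >= 0 && ii < nr) v = x(ii, jj);
        else if (ignore) continue;
        else v = pad;
        if (v < out(i, j)) out(i, j) = v;
      }
    }
  }
  return out;
}

// Maximum of x over the offset neighbourhood (grayscale dilation).
// [[Rcpp::export]]
NumericMatrix disc_max_filter(const NumericMatrix& x,
                              const IntegerVector& di,
                              const IntegerVector& dj,
                              double pad) {
  const int nr = x.nrow(), nc = x.ncol(), m = di.size();
  const bool ignore = NumericVector::is_na(pad);
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), R_NegInf);
  for (int k = 0; k < m; ++k) {
    const int a = di[k], b = dj[k];
    for (int j = 0; j < nc; ++j) {
      const int jj = j + b;
      const bool jin = (jj >= 0 && jj < nc);
      for (int i = 0; i < nr; ++i) {
        const int ii = i + a;
        double v;
        if (jin && ii >= 0 && ii < nr) v = x(ii, jj);
        else if (ignore) continue;
        else v = pad;
        if (v > out(i, j)) out(i, j) = v;
      }
    }
  }
  return out;
}
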