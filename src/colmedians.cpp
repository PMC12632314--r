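#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Per-sample (column) median of a channels x samples matrix; used for the
// global common median reference.
// [[Rcpp::export]]
NumericVector col_medians(const NumericMatrix& x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericVector out(nc);
  std::vector<double> buf(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) buf[i] = x(i, j);
    const int mid = nr / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double m = buf[mid];
    if (nr % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + mid);
      m = (m + lo) / 2.0;
    }
    out[j] = m;
  }
  return out;
}
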