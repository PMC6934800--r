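#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Column medians via nth_element; ties with base::median on even counts
// (mean of the two middle order statistics).
// [[Rcpp::export]]
NumericVector col_medians(NumericMatrix x) {
  const int n = x.nrow(), p = x.ncol();
  if (n == 0) stop("cannot take the median of zero rows");
  NumericVector out(p);
  std::vector<double> buf(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) buf[i] = x(i, j);
    const int h = n / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double m = buf[h];
    if (n % 2 == 0) {
      const double lo = *std::max_element(buf.begin(), buf.begin() + h);
      m = (m + lo) / 2.0;
    }
    out[j] = m;
  }
  return out;
}
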