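#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Column medians via nth_element; hot path of the robust resampling
// engine, where the MAD scale is recomputed for every resampled trait.
// [[Rcpp::export]]
NumericVector col_medians(NumericMatrix m) {
  const int n = m.nrow(), k = m.ncol();
  if (n < 1) stop("empty matrix");
  NumericVector out(k);
  std::vector<double> buf(n);
  const int h = n / 2;
  for (int j = 0; j < k; ++j) {
    std::copy(m.column(j).begin(), m.column(j).end(), buf.begin());
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double med = buf[h];
    if (n % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      med = (med + lo) / 2.0;
    }
    out[j] = med;
  }
  return out;
}
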