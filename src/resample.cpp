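#include <Rcpp.h>
using namespace Rcpp;

// n x B matrix whose columns are independent permutations of v, using
// R's RNG stream (reproducible under set.seed).
// [[Rcpp::export]]
NumericMatrix perm_columns(NumericVector v, int B) {
  const int n = v.size();
  NumericMatrix out(n, B);
  for (int b = 0; b < B; ++b) {
    NumericMatrix::Column col = out.column(b);
    std::copy(v.begin(), v.end(), col.begin());
    for (int i = n - 1; i > 0; --i) {          // Fisher-Yates
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(col[i], col[j]);
    }
  }
  return out;
}

// Huber psi applied columnwise: clip(m[, b] / sig[b]) at +/- c.
// [[Rcpp::export]]
NumericMatrix huber_psi_cols(NumericMatrix m, NumericVector sig, double c) {
  const int n = m.nrow(), B = m.ncol();
  if (sig.size() != B) stop("sig must have one entry per column");
  NumericMatrix out(n, B);
  for (int b = 0; b < B; ++b) {
    const double inv = 1.0 / sig[b];
    for (int i = 0; i < n; ++i) {
      double u = m(i, b) * inv;
      out(i, b) = u > c ? c : (u < -c ? -c : u);
    }
  }
  return out;
}
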