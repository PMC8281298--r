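#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of v, destroying its order; v must be non-empty
static double median_inplace(std::vector<double>& v) {
  const size_t n = v.size();
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  const double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  const double lo = *std::max_element(v.begin(), v.begin() + n / 2);
  return 0.5 * (lo + hi);
}

//' Row medians of a numeric matrix
//'
//' @param x numeric matrix with no missing values.
//' @return numeric vector of per-row medians.
//' @keywords internal
// [[Rcpp::export]]
NumericVector row_medians_cpp(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  if (nc == 0) stop("matrix has zero columns");
  NumericVector out(nr);
  std::vector<double> buf(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) buf[j] = x(i, j);
    out[i] = median_inplace(buf);
  }
  return out;
}

//' Row median absolute deviations
//'
//' MAD per row: median(|x - median(x)|) * constant.
//'
//' @param x numeric matrix with no missing values.
//' @param constant consistency constant (1.4826 for normal consistency).
//' @return numeric vector of per-row MADs.
//' @keywords internal
// [[Rcpp::export]]
NumericVector row_mads_cpp(NumericMatrix x, double constant) {
  const int nr = x.nrow(), nc = x.ncol();
  if (nc == 0) stop("matrix has zero columns");
  NumericVector out(nr);
  std::vector<double> buf(nc), dev(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) buf[j] = x(i, j);
    std::vector<double> tmp(buf);
    const double m = median_inplace(tmp);
    for (int j = 0; j < nc; ++j) dev[j] = std::abs(buf[j] - m);
    out[i] = constant * median_inplace(dev);
  }
  return out;
}
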