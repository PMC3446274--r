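#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// median of a scratch buffer, averaging the two central order statistics
// for even n (matches stats::median)
static double median_inplace(std::vector<double>& v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  const size_t mid = n / 2;
  std::nth_element(v.begin(), v.begin() + mid, v.end());
  double m = v[mid];
  if (n % 2 == 0) {
    const double lo = *std::max_element(v.begin(), v.begin() + mid);
    m = (m + lo) / 2.0;
  }
  return m;
}

// Per-row median and scaled MAD (constant * median(|x - median|)), with
// NA removal; the workhorse behind the COPA parameter fit.
// [[Rcpp::export]]
List row_median_mad(NumericMatrix x, double constant = 1.4826) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericVector med(nr), madv(nr);
  std::vector<double> buf;
  buf.reserve(nc);
  for (int i = 0; i < nr; ++i) {
    buf.clear();
    for (int j = 0; j < nc; ++j) {
      const double v = x(i, j);
      if (!NumericVector::is_na(v)) buf.push_back(v);
    }
    if (buf.empty()) {
      med[i] = NA_REAL;
      madv[i] = NA_REAL;
      continue;
    }
    const double m = median_inplace(buf);
    med[i] = m;
    for (size_t k = 0; k < buf.size(); ++k) buf[k] = std::fabs(buf[k] - m);
    madv[i] = constant * median_inplace(buf);
  }
  return List::create(_["median"] = med, _["mad"] = madv);
}
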