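#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Element-wise median across a list of equally sized numeric matrices.
// Used for the consensus of resampled TOM dissimilarities, where per-entry
// R-level median calls over n_gene^2 entries would dominate runtime.
// [[Rcpp::export(name = ".matrix_list_median")]]
NumericMatrix matrix_list_median(List mats) {
  int r = mats.size();
  if (r == 0) stop("empty matrix list");
  NumericMatrix first = mats[0];
  R_xlen_t n = first.size();
  std::vector<NumericMatrix> ms;
  ms.reserve(r);
  for (int k = 0; k < r; ++k) {
    NumericMatrix m = mats[k];
    if (m.size() != n || m.nrow() != first.nrow())
      stop("matrices must share dimensions");
    ms.push_back(m);
  }
  NumericMatrix out(first.nrow(), first.ncol());
  std::vector<double> buf(r);
  bool odd = (r % 2) == 1;
  int mid = r / 2;
  for (R_xlen_t i = 0; i < n; ++i) {
    for (int k = 0; k < r; ++k) buf[k] = ms[k][i];
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double hi = buf[mid];
    if (odd) {
      out[i] = hi;
    } else {
      double lo = *std::max_element(buf.begin(), buf.begin() + mid);
      out[i] = 0.5 * (lo + hi);
    }
  }
  out.attr("dimnames") = first.attr("dimnames");
  return out;
}
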