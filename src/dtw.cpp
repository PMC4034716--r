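#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Banded DTW, squared local cost, symmetric steps, sqrt of accumulated cost.
// A band of width w admits cells with |i - j| <= w - 1 (w = 1: diagonal only,
// which on equal lengths reduces to the Euclidean distance). Returns +Inf if
// the band admits no complete warping path.
// [[Rcpp::export]]
double dtw_dist_cpp(NumericVector a, NumericVector b, int width) {
  const int la = a.size(), lb = b.size();
  if (la == 0 || lb == 0) return NA_REAL;
  if (width < 1) width = 1;
  const int off = width - 1;
  if (std::abs(la - lb) > off) return R_PosInf;

  const double inf = R_PosInf;
  std::vector<double> prev(lb + 1, inf), cur(lb + 1, inf);
  prev[0] = 0.0;  // virtual origin; overwritten with inf after the first row
  for (int i = 1; i <= la; ++i) {
    std::fill(cur.begin(), cur.end(), inf);
    const int jlo = std::max(1, i - off);
    const int jhi = std::min(lb, i + off);
    for (int j = jlo; j <= jhi; ++j) {
      double d = a[i - 1] - b[j - 1];
      d *= d;
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = d + best;
    }
    std::swap(prev, cur);
    prev[0] = inf;
  }
  return std::sqrt(prev[lb]);
}

// DTW of a query against every length-l sliding window of a long series,
// one distance per admissible start (1-based starts 1 .. M - l + 1).
// [[Rcpp::export]]
NumericVector dtw_sliding_cpp(NumericVector query, NumericVector series,
                              int l, int width) {
  const int M = series.size();
  const int nw = M - l + 1;
  if (nw < 1) stop("window length exceeds the series length");
  NumericVector out(nw);
  for (int t = 0; t < nw; ++t) {
    NumericVector win(series.begin() + t, series.begin() + t + l);
    out[t] = dtw_dist_cpp(query, win, width);
  }
  return out;
}
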