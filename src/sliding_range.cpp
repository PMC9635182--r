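#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Temperature range (max - min) within a centred time window around each
// sample. Window membership is by timestamp, |t_j - t_i| <= halfwidth_s,
// so recording gaps shrink the window instead of borrowing samples across
// them. Monotonic-deque sliding extrema, O(n).
// [[Rcpp::export]]
NumericVector sliding_time_range(NumericVector time_s, NumericVector x,
                                 double halfwidth_s) {
  int n = time_s.size();
  if (x.size() != n) stop("time and value vectors differ in length");
  NumericVector out(n);
  std::deque<int> maxq, minq;
  int lo = 0, hi = -1;
  for (int i = 0; i < n; ++i) {
    while (hi + 1 < n && time_s[hi + 1] <= time_s[i] + halfwidth_s) {
      ++hi;
      while (!maxq.empty() && x[maxq.back()] <= x[hi]) maxq.pop_back();
      maxq.push_back(hi);
      while (!minq.empty() && x[minq.back()] >= x[hi]) minq.pop_back();
      minq.push_back(hi);
    }
    while (time_s[lo] < time_s[i] - halfwidth_s) {
      if (!maxq.empty() && maxq.front() == lo) maxq.pop_front();
      if (!minq.empty() && minq.front() == lo) minq.pop_front();
      ++lo;
    }
    out[i] = x[maxq.front()] - x[minq.front()];
  }
  return out;
}
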