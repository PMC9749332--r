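#include <Rcpp.h>
using namespace Rcpp;

// Exact penalized optimal partitioning of a two-channel series.
//
// Channel 1 (lrr) is observed at every marker; channel 2 (folded BAF) only at
// markers flagged heterozygous. The objective is
//   sum over segments of within-segment SSE (both channels) + penalty * K,
// with K the number of changepoints. Solved exactly by the O(n^2) dynamic
// program of optimal partitioning; segment costs come from prefix sums.
//
// [[Rcpp::export(name = ".dp_segment_cpp")]]
IntegerVector dp_segment_cpp(NumericVector y1, NumericVector y2,
                             IntegerVector het, double penalty) {
  int n = y1.size();
  if (n == 0) return IntegerVector(0);
  std::vector<double> s1(n + 1, 0.0), q1(n + 1, 0.0);
  std::vector<double> s2(n + 1, 0.0), q2(n + 1, 0.0);
  std::vector<double> ch(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + y1[i];
    q1[i + 1] = q1[i] + y1[i] * y1[i];
    double h = het[i] ? 1.0 : 0.0;
    double v = het[i] ? y2[i] : 0.0;
    s2[i + 1] = s2[i] + v;
    q2[i + 1] = q2[i] + v * v;
    ch[i + 1] = ch[i] + h;
  }
  std::vector<double> F(n + 1);
  std::vector<int> back(n + 1, 0);
  F[0] = -penalty;
  for (int j = 1; j <= n; ++j) {
    double best = R_PosInf;
    int arg = 0;
    for (int i = 0; i < j; ++i) {
      double m = (double)(j - i);
      double c = (q1[j] - q1[i]) - (s1[j] - s1[i]) * (s1[j] - s1[i]) / m;
      double nh = ch[j] - ch[i];
      if (nh > 0.0) {
        c += (q2[j] - q2[i]) - (s2[j] - s2[i]) * (s2[j] - s2[i]) / nh;
      }
      double cand = F[i] + c + penalty;
      if (cand < best) { best = cand; arg = i; }
    }
    F[j] = best;
    back[j] = arg;
  }
  // backtrack: collect segment end indices (1-based, inclusive)
  std::vector<int> ends;
  int j = n;
  while (j > 0) { ends.push_back(j); j = back[j]; }
  std::reverse(ends.begin(), ends.end());
  return wrap(ends);
}
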