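#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Greedy maximal interval-score extraction on a single chromosome.
//
// Score of interval [i, j]: S = sum(x[i..j]) / (sigma * sqrt(j - i + 1)).
// Repeatedly find the interval with maximal |S| inside the current segment
// (ties broken by leftmost start, then shortest length), record it when
// |S| >= threshold, and recurse on the flanks. Returns a matrix with
// 1-based columns (start, end, score).

struct Seg { int l, r; };

// [[Rcpp::export]]
NumericMatrix greedy_max_intervals(NumericVector x, double sigma,
                                   double threshold) {
  int n = x.size();
  std::vector<double> out_s, out_e, out_sc;
  if (n == 0 || sigma <= 0) stop("sigma must be > 0 and x non-empty");

  std::vector<double> pref(n + 1, 0.0);
  for (int i = 0; i < n; ++i) pref[i + 1] = pref[i] + x[i];
  std::vector<double> invs(n + 1, 0.0);
  for (int k = 1; k <= n; ++k) invs[k] = 1.0 / (sigma * std::sqrt((double)k));

  std::vector<Seg> stack;
  stack.push_back({0, n - 1});
  while (!stack.empty()) {
    Seg seg = stack.back();
    stack.pop_back();
    if (seg.l > seg.r) continue;
    double best = -1.0, best_score = 0.0;
    int bi = -1, bj = -1;
    for (int i = seg.l; i <= seg.r; ++i) {
      for (int j = i; j <= seg.r; ++j) {
        double s = (pref[j + 1] - pref[i]) * invs[j - i + 1];
        double a = std::fabs(s);
        if (a > best) {  // strict: keeps leftmost start, shortest length
          best = a;
          best_score = s;
          bi = i;
          bj = j;
        }
      }
    }
    if (best >= threshold) {
      out_s.push_back(bi + 1);
      out_e.push_back(bj + 1);
      out_sc.push_back(best_score);
      stack.push_back({seg.l, bi - 1});
      stack.push_back({bj + 1, seg.r});
    }
  }

  NumericMatrix res(out_s.size(), 3);
  for (size_t k = 0; k < out_s.size(); ++k) {
    res(k, 0) = out_s[k];
    res(k, 1) = out_e[k];
    res(k, 2) = out_sc[k];
  }
  colnames(res) = CharacterVector::create("start", "end", "score");
  return res;
}
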