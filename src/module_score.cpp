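#include <Rcpp.h>
using namespace Rcpp;

// Windowed composite-module score for a batch of promoters.
//
// Hits are given flat, sorted by (promoter, start): prom_off is the CSR
// offset vector (length n_prom + 1) into hit_start / hit_member, where
// hit_member is the 1-based index of the module member the hit belongs
// to (0 = not a member). The score of a promoter is
//   max over window starts s of sum_m weight[m] * min(count_m(s), maxcount[m])
// with count_m(s) the number of member-m hits starting in [s, s + W).
// Candidate starts are the hit starts themselves, clipped to len - W.
//
// [[Rcpp::export]]
NumericVector cpp_module_scores(IntegerVector prom_off,
                                IntegerVector hit_start,
                                IntegerVector hit_member,
                                NumericVector weight,
                                IntegerVector maxcount,
                                int window, int prom_len) {
  int n_prom = prom_off.size() - 1;
  int n_memb = weight.size();
  NumericVector out(n_prom);
  std::vector<int> cnt(n_memb);
  int max_start = prom_len - window;
  if (max_start < 0) max_start = 0;
  for (int p = 0; p < n_prom; ++p) {
    double best = 0.0;
    for (int i = prom_off[p]; i < prom_off[p + 1]; ++i) {
      if (hit_member[i] == 0) continue;
      int s = hit_start[i];
      if (s > max_start) s = max_start;
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int j = prom_off[p]; j < prom_off[p + 1]; ++j) {
        int m = hit_member[j];
        if (m == 0) continue;
        int t = hit_start[j];
        if (t >= s && t < s + window) cnt[m - 1]++;
      }
      double sc = 0.0;
      for (int m = 0; m < n_memb; ++m) {
        int c = cnt[m] < maxcount[m] ? cnt[m] : maxcount[m];
        sc += weight[m] * c;
      }
      if (sc > best) best = sc;
    }
    out[p] = best;
  }
  return out;
}
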