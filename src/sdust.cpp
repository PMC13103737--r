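#include <Rcpp.h>
using namespace Rcpp;

// Symmetric-DUST style low-complexity scan over triplet codes.
//
// trip: triplet codes 0..63 for each position i (triplet seq[i..i+2]),
//       -1 where any base in the triplet is not A/C/G/T (no triplet spans it).
// wt:   maximum window size in triplets (window bases - 2).
// threshold: integer T; a subinterval of k triplets with composition score
//       S = sum c_t (c_t - 1) / 2 has normalized score S / (k - 1); it is
//       reported as a perfect interval when the normalized score exceeds
//       T / 10 and no proper subinterval has a higher normalized score
//       (masks cover low-complexity cores, not whole windows that merely
//       contain one). Comparisons use doubled scores (2S) to stay integral
//       and cross-multiplication for exact rational ordering.
//
// Dynamic programme over the window band with rolling rows:
//   best(i, j) = max density over subintervals of [i, j]
//              = max(dens(i, j), best(i, j-1), best(i+1, j)),
// where best(i+1, .) is the previous row (i descending).
//
// Returns an integer matrix of merged [start, end) base intervals (0-based).
// [[Rcpp::export]]
IntegerMatrix sdust_scan_cpp(IntegerVector trip, int wt, int threshold) {
  int T = trip.size();
  if (T <= 0 || wt < 1) return IntegerMatrix(0, 2);
  std::vector<long> pn(wt, 0), pd(wt, 1);   // previous row best density
  std::vector<char> pv(wt, 0);              // previous row validity
  std::vector<long> cn(wt, 0), cd(wt, 1);
  std::vector<char> cv(wt, 0);
  std::vector<int> counts(64, 0);
  std::vector<char> mask(T + 2, 0);

  for (int i = T - 1; i >= 0; --i) {
    std::fill(cv.begin(), cv.end(), 0);
    if (trip[i] >= 0) {
      std::fill(counts.begin(), counts.end(), 0);
      long score2 = 0;
      int jend = std::min(T - 1, i + wt - 1);
      for (int j = i; j <= jend; ++j) {
        int c = trip[j];
        if (c < 0) break;
        score2 += 2L * counts[c];
        counts[c]++;
        int d = j - i;
        long den = d;  // k - 1
        long bnum = (den > 0) ? score2 : 0;
        long bden = (den > 0) ? den : 1;
        if (d > 0 && cv[d - 1] && cn[d - 1] * bden > bnum * cd[d - 1]) {
          bnum = cn[d - 1]; bden = cd[d - 1];    // best(i, j-1)
        }
        if (d > 0 && pv[d - 1] && pn[d - 1] * bden > bnum * pd[d - 1]) {
          bnum = pn[d - 1]; bden = pd[d - 1];    // best(i+1, j)
        }
        cn[d] = bnum; cd[d] = bden; cv[d] = 1;
        // Perfect: qualifies and own density >= best subinterval density.
        if (den > 0 && 10L * score2 > 2L * threshold * den &&
            score2 * bden >= bnum * den) {
          for (int b = i; b <= j + 2 && b < T + 2; ++b) mask[b] = 1;
        }
      }
    }
    std::swap(pn, cn); std::swap(pd, cd); std::swap(pv, cv);
  }
  // Collect merged [start, end) base intervals.
  std::vector<int> ms, me;
  int b = 0, n_bases = T + 2;
  while (b < n_bases) {
    if (mask[b]) {
      int s = b;
      while (b < n_bases && mask[b]) ++b;
      ms.push_back(s);
      me.push_back(b);
    } else {
      ++b;
    }
  }
  IntegerMatrix out(ms.size(), 2);
  for (size_t r = 0; r < ms.size(); ++r) {
    out(r, 0) = ms[r];
    out(r, 1) = me[r];
  }
  return out;
}
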