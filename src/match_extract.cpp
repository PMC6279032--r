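#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Greedy extraction of the best non-overlapping gapless diagonal segments
// of a score matrix. A segment occupies cells (i0+t, j0+t), t = 0..len-1.
// Repeatedly: among all segments of length >= min_len whose rows and
// columns are all still available, take the one with the largest total
// score (ties: smallest (i0, j0) lexicographically); mask its rows and
// columns. Stop when the best remaining segment has non-positive score or
// max_matches segments have been taken. Because masking only removes
// candidates, extraction order is non-increasing in score.
//
// Per diagonal the best segment ending at each cell is found with prefix
// sums and a running prefix minimum over admissible starts (O(L) per run);
// equal prefix minima keep the earliest start, preserving the
// lexicographic tie-break.

// [[Rcpp::export(name = ".extract_matches_cpp")]]
DataFrame extract_matches_cpp(NumericMatrix S, int min_len, int max_matches) {
  const int nr = S.nrow(), nc = S.ncol();
  std::vector<char> rmask(nr, 0), cmask(nc, 0);
  std::vector<int> out_i, out_j, out_len;
  std::vector<double> out_score;

  while ((int)out_i.size() < max_matches) {
    double best = 0.0;            // must beat 0: only positive segments
    int bi = -1, bj = -1, blen = 0;
    bool found = false;

    for (int d = -(nr - 1); d <= nc - 1; ++d) {
      int i = d < 0 ? -d : 0;
      int j = i + d;
      while (i < nr && j < nc) {
        if (rmask[i] || cmask[j]) { ++i; ++j; continue; }
        const int s0 = i;                       // run start (row index)
        std::vector<double> pre;                // prefix sums of the run
        pre.push_back(0.0);
        while (i < nr && j < nc && !rmask[i] && !cmask[j]) {
          pre.push_back(pre.back() + S(i, j));
          ++i; ++j;
        }
        const int L = (int)pre.size() - 1;
        if (L < min_len) continue;
        double minpre = pre[0];
        int minarg = 0;
        for (int e = min_len - 1; e < L; ++e) {
          const int scand = e - min_len + 1;    // newest admissible start
          if (pre[scand] < minpre) { minpre = pre[scand]; minarg = scand; }
          const double sum = pre[e + 1] - minpre;
          if (sum <= 0.0) continue;
          const int gi = s0 + minarg, gj = gi + d;
          const int len = e - minarg + 1;
          if (sum > best ||
              (found && sum == best &&
               (gi < bi || (gi == bi && gj < bj)))) {
            best = sum; bi = gi; bj = gj; blen = len; found = true;
          }
        }
      }
    }

    if (!found) break;
    out_i.push_back(bi + 1);                    // 1-based for R
    out_j.push_back(bj + 1);
    out_len.push_back(blen);
    out_score.push_back(best);
    for (int t = 0; t < blen; ++t) {
      rmask[bi + t] = 1;
      cmask[bj + t] = 1;
    }
  }

  return DataFrame::create(_["i0"] = out_i, _["j0"] = out_j,
                           _["len"] = out_len, _["score"] = out_score);
}
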