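#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with match +1, mismatch 0,
// linear gap -1, followed by a deterministic traceback that counts
// identical aligned positions. Traceback preference on score ties:
// diagonal, then up (gap in s2), then left (gap in s1), so co-optimal
// alignments always resolve to the same match count.

// [[Rcpp::export(name = ".nw_align_counts")]]
IntegerVector nw_align_counts(std::string s1, std::string s2) {
  const int n = s1.size(), m = s2.size();
  const int GAP = -1;
  std::vector<int> prev(m + 1), cur(m + 1);
  // full DP matrix needed for traceback; store as flat vector
  std::vector<int> H((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) H[j] = GAP * j;
  for (int i = 1; i <= n; ++i) {
    H[(size_t)i * (m + 1)] = GAP * i;
    for (int j = 1; j <= m; ++j) {
      int diag = H[(size_t)(i - 1) * (m + 1) + (j - 1)] +
                 (s1[i - 1] == s2[j - 1] ? 1 : 0);
      int up = H[(size_t)(i - 1) * (m + 1) + j] + GAP;
      int left = H[(size_t)i * (m + 1) + (j - 1)] + GAP;
      int best = diag >= up ? diag : up;
      if (left > best) best = left;
      H[(size_t)i * (m + 1) + j] = best;
    }
  }
  int i = n, j = m, matches = 0, aligned = 0;
  while (i > 0 || j > 0) {
    int here = H[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 &&
        here == H[(size_t)(i - 1) * (m + 1) + (j - 1)] +
                    (s1[i - 1] == s2[j - 1] ? 1 : 0)) {
      if (s1[i - 1] == s2[j - 1]) ++matches;
      --i; --j; ++aligned;
    } else if (i > 0 && here == H[(size_t)(i - 1) * (m + 1) + j] + GAP) {
      --i; ++aligned;
    } else {
      --j; ++aligned;
    }
  }
  return IntegerVector::create(_["score"] = H[(size_t)n * (m + 1) + m],
                               _["matches"] = matches,
                               _["aligned"] = aligned);
}
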