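#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Optimal string alignment (restricted Damerau-Levenshtein) distance:
// unit-cost substitutions, insertions, deletions and adjacent transpositions.
static int osa_dist(const std::string& a, const std::string& b, int cutoff) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  if (std::abs(n - m) > cutoff) return cutoff + 1;

  std::vector<int> prev2(m + 1), prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    int rowmin = cur[0];
    for (int j = 1; j <= m; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int v = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), prev[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        v = std::min(v, prev2[j - 2] + 1);
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (rowmin > cutoff) return cutoff + 1;  // band pruning
    std::swap(prev2, prev);
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".osa_distance")]]
IntegerVector osa_distance(std::string query, CharacterVector terms,
                           int cutoff = 1000000) {
  const int n = terms.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string t = as<std::string>(terms[i]);
    out[i] = osa_dist(query, t, cutoff);
  }
  return out;
}

// Normalized similarity 1 - d/max(len), vectorized over the vocabulary.
// [[Rcpp::export(name = ".osa_similarity")]]
NumericVector osa_similarity(std::string query, CharacterVector terms) {
  const int n = terms.size();
  const int lq = query.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string t = as<std::string>(terms[i]);
    int ml = std::max<int>(lq, t.size());
    if (ml == 0) { out[i] = 1.0; continue; }
    // anything below 0.8 similarity is discarded by callers; prune the DP
    int cutoff = ml;  // exact distance still required for reporting
    out[i] = 1.0 - double(osa_dist(query, t, cutoff)) / double(ml);
  }
  return out;
}
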