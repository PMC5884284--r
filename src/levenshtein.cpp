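#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Full dynamic-programming edit distance with unit-cost insertions,
// deletions and substitutions. Equal-length binary cluster labels only
// exercise substitutions, but the general form is implemented.
static int lev(const std::string& a, const std::string& b) {
  size_t la = a.size(), lb = b.size();
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (size_t j = 0; j <= lb; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= la; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= lb; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    prev.swap(cur);
  }
  return prev[lb];
}

// [[Rcpp::export]]
IntegerVector cpp_levenshtein(CharacterVector a, CharacterVector b,
                              bool substitution_only) {
  R_xlen_t n = std::max(a.size(), b.size());
  if (a.size() != b.size() && a.size() != 1 && b.size() != 1)
    stop("a and b must have equal length (or length 1)");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[a.size() == 1 ? 0 : i]);
    std::string sb = as<std::string>(b[b.size() == 1 ? 0 : i]);
    if (substitution_only) {
      if (sa.size() != sb.size())
        stop("substitution-only distance needs equal-length strings");
      int dist = 0;
      for (size_t j = 0; j < sa.size(); ++j) dist += (sa[j] != sb[j]);
      out[i] = dist;
    } else {
      out[i] = lev(sa, sb);
    }
  }
  return out;
}
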