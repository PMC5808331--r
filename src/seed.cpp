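#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

// Two-hit seeding: a query becomes a candidate against the target when two
// distinct k-mer word hits fall on nearby diagonals (within one band of
// width 'band'). Two staggered band gratings avoid boundary misses. Any
// alignment containing an exact run of k+1 nt or more produces two
// overlapping same-diagonal words, so everything but the most marginal
// local alignments seeds. Words containing N never match.

static inline bool encode_kmer(const char *s, int k, uint64_t &code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    int b;
    switch (s[i]) {
      case 'A': b = 0; break;
      case 'C': b = 1; break;
      case 'G': b = 2; break;
      case 'T': b = 3; break;
      default: return false;
    }
    code = (code << 2) | (uint64_t)b;
  }
  return true;
}

// [[Rcpp::export]]
LogicalVector seed_candidates(CharacterVector queries, std::string target,
                              int k, int band) {
  const int tlen = target.size();
  LogicalVector out(queries.size());
  if (tlen < k) return out;
  std::unordered_map<uint64_t, std::vector<int>> tindex;
  tindex.reserve(tlen * 2);
  for (int j = 0; j + k <= tlen; ++j) {
    uint64_t code;
    if (encode_kmer(target.c_str() + j, k, code)) tindex[code].push_back(j);
  }
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    const int qlen = q.size();
    bool cand = false;
    // band grating -> (last diag-band key seen with a different word hit)
    std::unordered_map<long long, int> seen1, seen2;
    for (int i = 0; i + k <= qlen && !cand; ++i) {
      uint64_t code;
      if (!encode_kmer(q.c_str() + i, k, code)) continue;
      auto it = tindex.find(code);
      if (it == tindex.end()) continue;
      for (int j : it->second) {
        int diag = i - j + tlen;     // non-negative
        long long key1 = diag / band;
        long long key2 = (diag + band / 2) / band;
        auto p1 = seen1.find(key1);
        if (p1 != seen1.end() && p1->second != j) { cand = true; break; }
        auto p2 = seen2.find(key2);
        if (p2 != seen2.end() && p2->second != j) { cand = true; break; }
        seen1[key1] = j;
        seen2[key2] = j;
      }
    }
    out[qi] = cand;
  }
  return out;
}
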