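#include <Rcpp.h>
#include <vector>
#include <array>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap penalty, returning all
// non-overlapping local alignments scoring >= min_score. After each
// accepted alignment its query rows and subject columns are masked and the
// DP is re-run (Waterman-Eggert style greedy iteration), so alternative
// alignments of the same pair never reuse aligned positions. 'N' mismatches
// every base including itself. Ties for the best cell are broken toward
// the smallest query end, then subject end, so results are deterministic.
//
// Returns a matrix with one row per alignment and columns:
// score, q_start, q_end, s_start, s_end (0-based half-open on the given
// strings), length (alignment columns), identities.

static inline uint8_t enc(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return 4;  // N and anything else
  }
}

// [[Rcpp::export]]
NumericMatrix sw_align_pair(std::string q, std::string s,
                            double match, double mismatch, double gap,
                            double min_score, int max_hits) {
  const int n = q.size(), m = s.size();
  std::vector<uint8_t> qe(n), se(m);
  for (int i = 0; i < n; ++i) qe[i] = enc(q[i]);
  for (int j = 0; j < m; ++j) se[j] = enc(s[j]);
  // 5x5 substitution table; N (code 4) mismatches everything
  double table[25];
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b)
      table[a * 5 + b] = (a == b && a < 4) ? match : mismatch;

  std::vector<char> ban_q(n, 0), ban_s(m, 0);
  std::vector<std::array<double, 7>> hits;

  // traceback codes: 0 stop, 1 diag, 2 from up (gap in subject), 3 from left
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  std::vector<double> prev(m + 1), cur(m + 1);

  for (int iter = 0; iter < max_hits; ++iter) {
    double best = 0.0; int bi = -1, bj = -1;
    std::fill(prev.begin(), prev.end(), 0.0);
    std::fill(tb.begin(), tb.end(), 0);
    for (int i = 1; i <= n; ++i) {
      const double *pp = prev.data();
      double *cc = cur.data();
      unsigned char *tbrow = tb.data() + (size_t)i * (m + 1);
      cc[0] = 0.0;
      if (ban_q[i - 1]) {
        std::fill(cc + 1, cc + m + 1, 0.0);
      } else {
        const double *srow = table + 5 * qe[i - 1];
        const char *bs = ban_s.data();
        double left = 0.0;
        for (int j = 1; j <= m; ++j) {
          double h = pp[j - 1] + srow[se[j - 1]];
          unsigned char t = 1;
          double u = pp[j] + gap;
          if (u > h) { h = u; t = 2; }
          double l = left + gap;
          if (l > h) { h = l; t = 3; }
          if (h <= 0.0 || bs[j - 1]) { h = 0.0; t = 0; }
          cc[j] = h; left = h;
          tbrow[j] = t;
          if (h > best) { best = h; bi = i; bj = j; }
        }
      }
      std::swap(prev, cur);
    }
    if (bi < 0 || best < min_score - 1e-9) break;

    // traceback from (bi, bj)
    int i = bi, j = bj, len = 0, ident = 0;
    while (i > 0 && j > 0) {
      unsigned char t = tb[(size_t)i * (m + 1) + j];
      if (t == 0) break;
      ++len;
      if (t == 1) {
        if (qe[i - 1] == se[j - 1] && qe[i - 1] < 4) ++ident;
        --i; --j;
      } else if (t == 2) --i;
      else --j;
    }
    // mask aligned query rows and subject columns
    for (int k = i; k < bi; ++k) ban_q[k] = 1;
    for (int k = j; k < bj; ++k) ban_s[k] = 1;
    hits.push_back({best, (double)i, (double)bi, (double)j, (double)bj,
                    (double)len, (double)ident});
  }

  NumericMatrix out(hits.size(), 7);
  for (size_t r = 0; r < hits.size(); ++r)
    for (int c = 0; c < 7; ++c) out(r, c) = hits[r][c];
  colnames(out) = CharacterVector::create("score", "q_start", "q_end",
                                          "s_start", "s_end", "length",
                                          "identities");
  return out;
}
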