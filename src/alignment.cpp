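#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Fit alignment of the shorter sequence against the longer one:
// the shorter is aligned globally, end gaps on the longer are free.
// Scoring: match +1, mismatch -1, gap -2 per position (linear).
// Among all optimal-score alignments we take the one with the most
// identical bases, by maximizing score*1024 + matches lexicographically
// (lengths are capped so the packing cannot overflow; the cap comfortably
// covers reads and the longest contigs this pipeline handles).
//
// Returns matches in the chosen alignment; identity = matches / shorter len.

static const int64_t PACK = 1 << 18; // > max matches for sequences < 262144 nt

static int64_t fit_matches(const std::string &shorter, const std::string &longer) {
  const int m = (int)shorter.size();
  const int n = (int)longer.size();
  const int64_t GAP = -2 * PACK;        // gap: score -2, matches +0
  // two-row DP over combined value
  std::vector<int64_t> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = 0;  // free leading gaps in longer
  for (int i = 1; i <= m; ++i) {
    cur[0] = (int64_t)i * GAP;               // gaps in shorter are penalized
    const char a = shorter[i - 1];
    for (int j = 1; j <= n; ++j) {
      const bool eq = (a == longer[j - 1]);
      int64_t diag = prev[j - 1] + (eq ? (PACK + 1) : -PACK);
      int64_t up   = prev[j] + GAP;
      int64_t left = cur[j - 1] + GAP;
      int64_t best = diag > up ? diag : up;
      if (left > best) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  int64_t best = prev[0];
  for (int j = 1; j <= n; ++j) if (prev[j] > best) best = prev[j];
  int64_t matches = ((best % PACK) + PACK) % PACK;
  return matches;
}

// [[Rcpp::export(name = ".nw_identity_cpp")]]
double nw_identity_cpp(std::string a, std::string b) {
  if (a.empty() || b.empty())
    stop("sequences must be non-empty");
  if (a.size() >= PACK || b.size() >= PACK)
    stop("sequences longer than %d nt are not supported by the DP kernel", (int)PACK - 1);
  if (a.size() == b.size()) {
    // equal lengths: the free end gaps sit on whichever sequence plays the
    // "longer" role, so evaluate both roles and keep the better fit; this
    // makes the identity symmetric in its arguments
    int64_t m = std::max(fit_matches(a, b), fit_matches(b, a));
    return (double)m / (double)a.size();
  }
  const std::string &shorter = (a.size() < b.size()) ? a : b;
  const std::string &longer  = (a.size() < b.size()) ? b : a;
  int64_t matches = fit_matches(shorter, longer);
  return (double)matches / (double)shorter.size();
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Number of k-mer start positions in `a` whose k-mer occurs anywhere in `b`.
// Over-counts shared k-mers (repeats in b counted once per a-position), which
// keeps the clustering prescreen conservative: it can only admit extra
// candidate pairs, never drop a pair that could pass the identity threshold.
// [[Rcpp::export(name = ".shared_kmers_cpp")]]
int shared_kmers_cpp(std::string a, std::string b, int k) {
  if (k < 1 || k > 15) stop("k must be in [1, 15]");
  if ((int)a.size() < k || (int)b.size() < k) return 0;
  const uint32_t mask = (1u << (2 * k)) - 1u;
  std::vector<bool> seen(mask + 1u, false);
  uint32_t code = 0; int run = 0;
  for (size_t i = 0; i < b.size(); ++i) {
    int c = base_code(b[i]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)c) & mask;
    if (++run >= k) seen[code] = true;
  }
  int count = 0; code = 0; run = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int c = base_code(a[i]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)c) & mask;
    if (++run >= k && seen[code]) ++count;
  }
  return count;
}
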