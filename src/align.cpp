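#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cstdlib>

using namespace Rcpp;

// Unit-cost Levenshtein distance, two-row DP.  Used for candidate-path
// selection against the original read segment.
// [[Rcpp::export]]
int cpp_levenshtein(std::string a, std::string b) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    const char ca = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + (ca == b[j - 1] ? 0 : 1);
      int u = prev[j] + 1;
      int l = cur[j - 1] + 1;
      if (u < d) d = u;
      if (l < d) d = l;
      cur[j] = d;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

namespace {

const int BIG = 1 << 28;

// Banded global alignment of read (columns) against ref (rows) around
// the straight diagonal, half-width w.  Fills `status` (one logical per
// reference locus: aligned to exactly one matching nucleotide) and
// returns true unless the optimal path touched the band boundary, in
// which case the caller should widen the band and retry: a path strictly
// inside the band is optimal over the whole matrix.
bool banded_status(const std::string& ref, const std::string& read, int w,
                   std::vector<int>& status) {
  const int n = (int)ref.size(), m = (int)read.size();
  const int W = 2 * w + 1;
  auto center = [&](int i) { return (int)((long long)i * m / n); };
  std::vector<int> prev(W), cur(W);
  std::vector<uint8_t> tb((size_t)(n + 1) * W); // 0 diag, 1 up, 2 left
  // row 0
  int c0 = 0;
  for (int idx = 0; idx < W; ++idx) {
    int j = c0 - w + idx;
    prev[idx] = (j >= 0 && j <= m) ? j : BIG;
    tb[idx] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    const int ci = center(i), cp = center(i - 1);
    const int shift = ci - cp; // prev-row index offset for same j
    const char cr = ref[i - 1];
    uint8_t* tbrow = &tb[(size_t)i * W];
    for (int idx = 0; idx < W; ++idx) {
      int j = ci - w + idx;
      if (j < 0 || j > m) { cur[idx] = BIG; continue; }
      int pd = idx + shift - 1; // prev row, column j-1
      int pu = idx + shift;     // prev row, column j
      int diag = (j >= 1 && pd >= 0 && pd < W) ? prev[pd] : BIG;
      int up = (pu >= 0 && pu < W) ? prev[pu] : BIG;
      int left = (idx >= 1) ? cur[idx - 1] : BIG;
      int d = diag < BIG ? diag + (cr == read[j - 1] ? 0 : 1) : BIG;
      int u = up < BIG ? up + 1 : BIG;
      int l = left < BIG ? left + 1 : BIG;
      uint8_t op = 0;
      int best = d;
      if (u < best) { best = u; op = 1; }
      if (l < best) { best = l; op = 2; }
      cur[idx] = best;
      tbrow[idx] = op;
    }
    std::swap(prev, cur);
  }
  if (prev[m - center(n) + w] >= BIG) return false;
  // traceback
  int i = n, j = m;
  bool touched = false;
  while (i > 0 || j > 0) {
    int ci = (i > 0) ? center(i) : 0;
    int idx = j - (ci - w);
    if (i > 0 && ((idx == 0 && j > 0) || (idx == W - 1 && j < m)))
      touched = true;
    uint8_t op = (i == 0) ? 2 : tb[(size_t)i * W + idx];
    if (j == 0) op = 1;
    if (op == 0) {
      status[i - 1] = (ref[i - 1] == read[j - 1]) ? 1 : 0;
      --i; --j;
    } else if (op == 1) {
      status[i - 1] = 0; // reference locus deleted in the read
      --i;
    } else {
      --j; // insertion in the read: no reference locus
    }
  }
  return !touched;
}

} // namespace

// Global edit-distance alignment of a read against its true reference
// interval, banded with an adaptive band: the band is doubled and the
// alignment redone whenever the optimal banded path touches the band
// boundary, so the reported alignment is a true global optimum.  Returns
// one logical per *reference* locus: TRUE iff that locus aligns to
// exactly one read nucleotide that matches it.  Mismatched or deleted
// reference loci are FALSE; read insertions consume no reference locus.
// Traceback prefers diagonal, then reference-deletion, then insertion,
// making locus calls deterministic.
// [[Rcpp::export]]
LogicalVector cpp_align_ref_status(std::string ref, std::string read) {
  const int n = (int)ref.size(), m = (int)read.size();
  LogicalVector out(n);
  if (n == 0) return out;
  if (m == 0) {
    for (int i = 0; i < n; ++i) out[i] = false;
    return out;
  }
  std::vector<int> status(n, 0);
  int w = std::abs(n - m) + 32;
  const int wmax = std::max(n, m);
  for (;;) {
    if (banded_status(ref, read, w, status)) break;
    if (w >= wmax) { banded_status(ref, read, wmax + 1, status); break; }
    w = std::min(2 * w, wmax);
  }
  for (int i = 0; i < n; ++i) out[i] = status[i] != 0;
  return out;
}

// Best-prefix fit of a candidate path against an original segment:
// returns the minimal Levenshtein distance over all prefixes of
// `candidate` and the longest prefix length attaining it.  Used to trim
// seed-and-extend candidates, which stop at a length bound rather than
// at an anchor.
// [[Rcpp::export]]
List cpp_best_prefix(std::string original, std::string candidate) {
  const int n = (int)original.size(), m = (int)candidate.size();
  // final DP row holds lev(original, candidate[0..j]) for every j
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    const char ca = original[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + (ca == candidate[j - 1] ? 0 : 1);
      int u = prev[j] + 1;
      int l = cur[j - 1] + 1;
      if (u < d) d = u;
      if (l < d) d = l;
      cur[j] = d;
    }
    std::swap(prev, cur);
  }
  int best = prev[0], best_j = 0;
  for (int j = 1; j <= m; ++j)
    if (prev[j] <= best) { best = prev[j]; best_j = j; }
  return List::create(_["distance"] = best, _["prefix_len"] = best_j);
}
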