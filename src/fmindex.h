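#ifndef LRBRIDGE_FMINDEX_H
#define LRBRIDGE_FMINDEX_H

#include <cstdint>
#include <vector>
#include <array>
#include <string>

// Alphabet order is fixed: $ < A < C < G < N < T (indices 0..5).
// '$' marks read terminators in the multi-string BWT; it never occurs in
// queries.
static const char LR_ALPHA[6] = {'$', 'A', 'C', 'G', 'N', 'T'};

inline int lr_sym(char c) {
  switch (c) {
    case '$': return 0;
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 3;
    case 'N': return 4;
    case 'T': return 5;
  }
  return -1;
}

// Watson-Crick complement on symbol indices; N is self-complementary.
inline int lr_comp(int s) {
  switch (s) {
    case 1: return 5;
    case 2: return 3;
    case 3: return 2;
    case 4: return 4;
    case 5: return 1;
  }
  return -1;
}

class FmIndex {
public:
  std::vector<uint8_t> bwt;    // decoded BWT, symbol indices 0..5
  uint64_t n = 0;              // BWT length
  std::array<uint64_t, 7> C{}; // C[c] = number of symbols strictly < c

  virtual ~FmIndex() {}
  virtual uint64_t rank(int c, uint64_t p) const = 0;

  // Backward search over one strand; syms[0..k-1] are indices 1..5.
  double count_syms(const int* syms, int k) const {
    uint64_t lo = 0, hi = n;
    for (int i = k - 1; i >= 0; --i) {
      int c = syms[i];
      lo = C[c] + rank(c, lo);
      hi = C[c] + rank(c, hi);
      if (lo >= hi) return 0.0;
    }
    return static_cast<double>(hi - lo);
  }

  // Forward strand plus reverse complement, summed (the unconditional
  // both-strand counting rule).
  double count_both(const int* syms, int k) const {
    double fwd = count_syms(syms, k);
    uint64_t lo = 0, hi = n;
    double rc = 0.0;
    // reverse complement read backwards == complement read forwards
    for (int i = 0; i < k; ++i) {
      int c = lr_comp(syms[i]);
      lo = C[c] + rank(c, lo);
      hi = C[c] + rank(c, hi);
      if (lo >= hi) { lo = hi; break; }
    }
    if (hi > lo) rc = static_cast<double>(hi - lo);
    return fwd + rc;
  }
};

#endif
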