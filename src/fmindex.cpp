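#include <Rcpp.h>
#include <cstring>
#include "fmindex.h"

using namespace Rcpp;

// Default implementation: one bit plane per symbol with a cumulative
// popcount per 64-bit word, giving O(1) rank at ~1.1 bits+counts per
// BWT symbol per plane.  Fast, memory-hungrier.
class BitArrayFm : public FmIndex {
public:
  std::vector<std::vector<uint64_t>> bits;  // [6][nwords]
  std::vector<std::vector<uint32_t>> cum;   // [6][nwords+1]

  void build() {
    size_t nwords = (n + 63) / 64;
    bits.assign(6, std::vector<uint64_t>(nwords, 0));
    cum.assign(6, std::vector<uint32_t>(nwords + 1, 0));
    for (uint64_t i = 0; i < n; ++i)
      bits[bwt[i]][i >> 6] |= (uint64_t)1 << (i & 63);
    for (int c = 0; c < 6; ++c)
      for (size_t w = 0; w < nwords; ++w)
        cum[c][w + 1] = cum[c][w] + (uint32_t)__builtin_popcountll(bits[c][w]);
  }

  uint64_t rank(int c, uint64_t p) const override {
    uint64_t w = p >> 6, r = p & 63;
    uint64_t x = cum[c][w];
    if (r) x += __builtin_popcountll(bits[c][w] & (((uint64_t)1 << r) - 1));
    return x;
  }
};

// Alternative implementation: occurrence checkpoints every `rate`
// positions plus a linear scan of the stored BWT.  Slower, smaller.
class SampledFm : public FmIndex {
public:
  int rate = 128;
  std::vector<uint32_t> ck; // [(n/rate)+1][6], row-major

  void build() {
    size_t nck = n / rate + 1;
    ck.assign(nck * 6, 0);
    uint32_t occ[6] = {0, 0, 0, 0, 0, 0};
    for (uint64_t i = 0; i < n; ++i) {
      if (i % rate == 0) std::memcpy(&ck[(i / rate) * 6], occ, sizeof(occ));
      occ[bwt[i]]++;
    }
    if (n % rate == 0 && n > 0)
      std::memcpy(&ck[(n / rate) * 6], occ, sizeof(occ));
    else if (n == 0)
      std::memset(ck.data(), 0, sizeof(uint32_t) * 6);
  }

  uint64_t rank(int c, uint64_t p) const override {
    uint64_t q = p / rate;
    uint64_t x = ck[q * 6 + c];
    for (uint64_t i = q * rate; i < p; ++i)
      if (bwt[i] == c) ++x;
    return x;
  }
};

static FmIndex* get_fm(SEXP ptr) {
  Rcpp::XPtr<FmIndex> xp(ptr);
  return xp.get();
}

// [[Rcpp::export]]
SEXP cpp_fm_build(IntegerVector run_symbols, NumericVector run_lengths,
                  std::string implementation, int sample_rate) {
  FmIndex* fm;
  if (implementation == "bitarray")
    fm = new BitArrayFm();
  else {
    SampledFm* s = new SampledFm();
    s->rate = sample_rate;
    fm = s;
  }
  uint64_t n = 0;
  for (R_xlen_t i = 0; i < run_lengths.size(); ++i) n += (uint64_t)run_lengths[i];
  fm->bwt.reserve(n);
  for (R_xlen_t i = 0; i < run_symbols.size(); ++i) {
    uint64_t l = (uint64_t)run_lengths[i];
    for (uint64_t j = 0; j < l; ++j) fm->bwt.push_back((uint8_t)run_symbols[i]);
  }
  fm->n = n;
  uint64_t tot[6] = {0, 0, 0, 0, 0, 0};
  for (uint8_t s : fm->bwt) tot[s]++;
  fm->C[0] = 0;
  for (int c = 0; c < 6; ++c) fm->C[c + 1] = fm->C[c] + tot[c];
  if (implementation == "bitarray")
    static_cast<BitArrayFm*>(fm)->build();
  else
    static_cast<SampledFm*>(fm)->build();
  Rcpp::XPtr<FmIndex> xp(fm, true);
  return xp;
}

// [[Rcpp::export]]
double cpp_fm_rank(SEXP ptr, int symbol, double p) {
  FmIndex* fm = get_fm(ptr);
  if (symbol < 0 || symbol > 5) stop("symbol index out of range");
  if (p < 0 || p > (double)fm->n) stop("rank position out of range");
  return (double)fm->rank(symbol, (uint64_t)p);
}

// [[Rcpp::export]]
NumericVector cpp_fm_offsets(SEXP ptr) {
  FmIndex* fm = get_fm(ptr);
  NumericVector out(7);
  for (int i = 0; i < 7; ++i) out[i] = (double)fm->C[i];
  return out;
}

static std::vector<int> to_syms(const char* s, int k) {
  std::vector<int> v(k);
  for (int i = 0; i < k; ++i) {
    int c = lr_sym(s[i]);
    if (c < 1) stop("k-mer contains a character outside A/C/G/N/T");
    v[i] = c;
  }
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_count_kmers(SEXP ptr, CharacterVector kmers) {
  FmIndex* fm = get_fm(ptr);
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    SEXP s = STRING_ELT(kmers, i);
    std::vector<int> syms = to_syms(CHAR(s), LENGTH(s));
    out[i] = fm->count_both(syms.data(), (int)syms.size());
  }
  return out;
}

// Per-position both-strand counts of all k-mers of a read; one entry per
// k-mer start, length nchar(read) - k + 1.
// [[Rcpp::export]]
NumericVector cpp_read_kmer_counts(SEXP ptr, std::string read, int k) {
  FmIndex* fm = get_fm(ptr);
  int len = (int)read.size();
  if (len < k) return NumericVector(0);
  std::vector<int> syms = to_syms(read.c_str(), len);
  NumericVector out(len - k + 1);
  for (int i = 0; i + k <= len; ++i)
    out[i] = fm->count_both(syms.data() + i, k);
  return out;
}

// Frequencies of the four single-base extensions of a k-mer (same k:
// shift off one base, append the candidate).  Zero-frequency bases are
// kept here; the R wrapper drops them.
// [[Rcpp::export]]
NumericVector cpp_extend_kmer(SEXP ptr, std::string kmer, bool right) {
  FmIndex* fm = get_fm(ptr);
  int k = (int)kmer.size();
  std::vector<int> syms = to_syms(kmer.c_str(), k);
  static const int BASES[4] = {1, 2, 3, 5}; // A, C, G, T
  NumericVector out(4);
  std::vector<int> cand(k);
  for (int b = 0; b < 4; ++b) {
    if (right) {
      for (int i = 1; i < k; ++i) cand[i - 1] = syms[i];
      cand[k - 1] = BASES[b];
    } else {
      cand[0] = BASES[b];
      for (int i = 0; i < k - 1; ++i) cand[i + 1] = syms[i];
    }
    out[b] = fm->count_both(cand.data(), k);
  }
  return out;
}
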