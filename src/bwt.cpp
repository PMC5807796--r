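#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include "fmindex.h"

using namespace Rcpp;

// Multi-string BWT by direct suffix sort of the concatenation
// r_0 $_0 r_1 $_1 ... with per-string terminators that sort below every
// base and among themselves by string index.  Terminators are unique, so
// suffix comparisons always resolve within one read and the sort order
// equals the rotation-sort order with the same tie rule.
// [[Rcpp::export]]
List cpp_build_msbwt(CharacterVector reads) {
  const int64_t m = reads.size();
  int64_t n = 0;
  for (int64_t i = 0; i < m; ++i) n += LENGTH(STRING_ELT(reads, i)) + 1;

  std::vector<int32_t> text(static_cast<size_t>(n));
  {
    int64_t pos = 0, sidx = 0;
    for (int64_t i = 0; i < m; ++i) {
      SEXP s = STRING_ELT(reads, i);
      const char* p = CHAR(s);
      const int len = LENGTH(s);
      if (len == 0) stop("read %d is empty", (int)(i + 1));
      for (int j = 0; j < len; ++j) {
        int sym = lr_sym(p[j]);
        if (sym < 1)
          stop("read %d contains a character outside A/C/G/N/T at position %d",
               (int)(i + 1), j + 1);
        text[pos++] = (int32_t)m + sym - 1; // bases sort above all terminators
      }
      text[pos++] = (int32_t)sidx++; // unique terminator, ordered by index
    }
  }

  std::vector<int32_t> sa(static_cast<size_t>(n));
  for (int64_t i = 0; i < n; ++i) sa[i] = (int32_t)i;
  const int32_t* tx = text.data();
  std::sort(sa.begin(), sa.end(), [tx](int32_t a, int32_t b) {
    for (;;) {
      int32_t va = tx[a], vb = tx[b];
      if (va != vb) return va < vb;
      ++a; ++b;
    }
  });

  // Last column; any terminator predecessor emits '$'.
  std::vector<int> run_sym;
  std::vector<double> run_len;
  std::array<double, 6> totals{};
  for (int64_t i = 0; i < n; ++i) {
    int64_t p = sa[i] == 0 ? n - 1 : sa[i] - 1;
    int sym = text[p] < m ? 0 : (int)(text[p] - m + 1);
    totals[sym] += 1.0;
    if (!run_sym.empty() && run_sym.back() == sym)
      run_len.back() += 1.0;
    else {
      run_sym.push_back(sym);
      run_len.push_back(1.0);
    }
  }

  return List::create(
      _["run_symbols"] = IntegerVector(run_sym.begin(), run_sym.end()),
      _["run_lengths"] = NumericVector(run_len.begin(), run_len.end()),
      _["total_counts"] = NumericVector(totals.begin(), totals.end()),
      _["num_strings"] = (double)m, _["length"] = (double)n);
}

// On-disk run-length dialect: one byte per chunk; low 3 bits = symbol
// index (0..5), high 5 bits = a 5-bit length chunk.  Consecutive bytes
// carrying the same symbol extend the run: length += chunk << (5*j) for
// the j-th continuation byte.
// [[Rcpp::export]]
RawVector cpp_rle_to_bytes(IntegerVector run_symbols, NumericVector run_lengths) {
  std::vector<uint8_t> out;
  out.reserve(run_symbols.size());
  for (R_xlen_t i = 0; i < run_symbols.size(); ++i) {
    int sym = run_symbols[i];
    double len = run_lengths[i];
    if (sym < 0 || sym > 5) stop("symbol index out of range in run %d", (int)(i + 1));
    if (len < 1) stop("non-positive run length in run %d", (int)(i + 1));
    uint64_t l = (uint64_t)len;
    do {
      out.push_back((uint8_t)((sym & 7) | ((l & 31) << 3)));
      l >>= 5;
    } while (l > 0);
  }
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export]]
List cpp_bytes_to_rle(RawVector bytes) {
  std::vector<int> run_sym;
  std::vector<double> run_len;
  std::array<double, 6> totals{};
  int prev_sym = -1;
  int shift = 0;
  int64_t run_start = 0;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    uint8_t b = bytes[i];
    int sym = b & 7;
    uint64_t chunk = b >> 3;
    if (sym > 5)
      stop("undecodable symbol index %d at byte offset %d", sym, (int)i);
    if (sym == prev_sym) {
      shift += 5;
      run_len.back() += (double)(chunk << shift);
      totals[sym] += (double)(chunk << shift);
    } else {
      if (!run_sym.empty() && run_len.back() == 0)
        stop("zero-length run at byte offset %d", (int)run_start);
      run_sym.push_back(sym);
      run_len.push_back((double)chunk);
      totals[sym] += (double)chunk;
      prev_sym = sym;
      shift = 0;
      run_start = i;
    }
  }
  if (!run_sym.empty() && run_len.back() == 0)
    stop("zero-length run at byte offset %d", (int)run_start);
  double n = 0;
  for (double t : totals) n += t;
  return List::create(
      _["run_symbols"] = IntegerVector(run_sym.begin(), run_sym.end()),
      _["run_lengths"] = NumericVector(run_len.begin(), run_len.end()),
      _["total_counts"] = NumericVector(totals.begin(), totals.end()),
      _["num_strings"] = totals[0], _["length"] = n);
}
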