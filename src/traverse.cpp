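#include <Rcpp.h>
#include "fmindex.h"

using namespace Rcpp;

// Depth-first traversal of the implicit de Bruijn graph.  Nodes are
// k-mers with both-strand frequency >= t; edges follow (k-1)-overlaps in
// A<C<G<T order.  The branch budget charges one unit at every node with
// >= 2 qualifying successors; exceeding it aborts the whole traversal,
// keeping whatever complete paths were already found.
namespace {

const int BASES[4] = {1, 2, 3, 5}; // A, C, G, T

struct Traverser {
  const FmIndex* fm;
  int k;
  double t;
  long budget;
  size_t min_len, max_len, max_paths;
  bool bridge_mode;
  std::vector<int> target; // bridge only
  std::vector<int> path;
  std::vector<std::string> seqs;
  std::vector<double> minfreqs;
  bool exhausted = false;
  bool done = false;

  bool ends_with_target() const {
    size_t L = path.size(), K = target.size();
    if (L < K) return false;
    for (size_t i = 0; i < K; ++i)
      if (path[L - K + i] != target[i]) return false;
    return true;
  }

  void record(double minf) {
    std::string s(path.size(), 'N');
    for (size_t i = 0; i < path.size(); ++i) s[i] = LR_ALPHA[path[i]];
    seqs.push_back(s);
    minfreqs.push_back(minf);
    if (seqs.size() >= max_paths) done = true;
  }

  void dfs(double minf) {
    if (done) return;
    size_t len = path.size();
    if (bridge_mode) {
      if (len >= min_len && len <= max_len && ends_with_target()) {
        record(minf);
        if (done) return;
      }
      if (len >= max_len) return;
    } else {
      if (len >= max_len) { record(minf); return; }
    }
    double cnt[4];
    int nq = 0;
    std::vector<int> cand(k);
    for (int i = 1; i < k; ++i) cand[i - 1] = path[len - k + i];
    for (int b = 0; b < 4; ++b) {
      cand[k - 1] = BASES[b];
      cnt[b] = fm->count_both(cand.data(), k);
      if (cnt[b] >= t) ++nq;
    }
    if (nq == 0) {
      if (!bridge_mode && len >= min_len) record(minf);
      return;
    }
    if (nq >= 2) {
      if (--budget < 0) {
        exhausted = true;
        done = true;
        return;
      }
    }
    for (int b = 0; b < 4 && !done; ++b) {
      if (cnt[b] >= t) {
        path.push_back(BASES[b]);
        dfs(cnt[b] < minf ? cnt[b] : minf);
        path.pop_back();
      }
    }
  }
};

std::vector<int> str_syms(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = lr_sym(s[i]);
    if (c < 1) stop("k-mer contains a character outside A/C/G/N/T");
    v[i] = c;
  }
  return v;
}

std::vector<int> rc_syms(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) r[i] = lr_comp(v[v.size() - 1 - i]);
  return r;
}

std::string rc_string(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    r[i] = LR_ALPHA[lr_comp(lr_sym(s[s.size() - 1 - i]))];
  return r;
}

List run_bridge(const FmIndex* fm, const std::vector<int>& seed,
                const std::vector<int>& target, double t, double L,
                double min_len, double max_len, int max_paths,
                bool* exhausted) {
  Traverser tr;
  tr.fm = fm;
  tr.k = (int)seed.size();
  tr.t = t;
  tr.budget = (long)L;
  tr.min_len = (size_t)min_len;
  tr.max_len = (size_t)max_len;
  tr.max_paths = (size_t)max_paths;
  tr.bridge_mode = true;
  tr.target = target;
  tr.path = seed;
  double seed_cnt = fm->count_both(seed.data(), tr.k);
  tr.dfs(seed_cnt);
  *exhausted = tr.exhausted;
  return List::create(_["sequences"] = tr.seqs, _["min_freqs"] = tr.minfreqs);
}

} // namespace

// [[Rcpp::export]]
List cpp_bridge(SEXP ptr, std::string seed, std::string target, double t,
                double branch_limit, double min_len, double max_len,
                int max_paths) {
  Rcpp::XPtr<FmIndex> fm(ptr);
  std::vector<int> s = str_syms(seed), g = str_syms(target);
  if (s.size() != g.size()) stop("seed and target must have equal length");
  bool exhausted = false, reversed = false;
  List res = run_bridge(fm.get(), s, g, t, branch_limit, min_len, max_len,
                        max_paths, &exhausted);
  std::vector<std::string> seqs = as<std::vector<std::string>>(res["sequences"]);
  std::vector<double> mf = as<std::vector<double>>(res["min_freqs"]);
  if (seqs.empty()) {
    // reverse bridging: extend from the reverse complement of the target
    // toward the reverse complement of the seed, then flip the results
    bool ex2 = false;
    List r2 = run_bridge(fm.get(), rc_syms(g), rc_syms(s), t, branch_limit,
                         min_len, max_len, max_paths, &ex2);
    std::vector<std::string> s2 = as<std::vector<std::string>>(r2["sequences"]);
    if (!s2.empty()) {
      reversed = true;
      mf = as<std::vector<double>>(r2["min_freqs"]);
      seqs.clear();
      for (auto& q : s2) seqs.push_back(rc_string(q));
    }
    exhausted = exhausted || ex2;
  }
  return List::create(_["sequences"] = seqs, _["min_freqs"] = mf,
                      _["exhausted"] = exhausted, _["reversed"] = reversed);
}

// [[Rcpp::export]]
List cpp_extend_paths(SEXP ptr, std::string seed, double t,
                      double branch_limit, double min_len, double max_len,
                      int max_paths, bool head) {
  Rcpp::XPtr<FmIndex> fm(ptr);
  std::vector<int> s = str_syms(seed);
  if (head) s = rc_syms(s); // leftward = rightward on the other strand
  Traverser tr;
  tr.fm = fm.get();
  tr.k = (int)s.size();
  tr.t = t;
  tr.budget = (long)branch_limit;
  tr.min_len = (size_t)min_len;
  tr.max_len = (size_t)max_len;
  tr.max_paths = (size_t)max_paths;
  tr.bridge_mode = false;
  tr.path = s;
  double seed_cnt = fm->count_both(s.data(), tr.k);
  tr.dfs(seed_cnt);
  std::vector<std::string> seqs = tr.seqs;
  if (head)
    for (auto& q : seqs) q = rc_string(q);
  return List::create(_["sequences"] = seqs, _["min_freqs"] = tr.minfreqs,
                      _["exhausted"] = tr.exhausted);
}
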