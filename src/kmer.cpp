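// Gapped k-mer featurisation, streaming class statistics for linear-model
// training, and linear scoring.  A feature is a choice of k informative
// positions out of an l-bp window (a "gap pattern") plus the k bases at
// those positions; its id is pattern_index * 4^k + word, with the word
// reading the informative bases 5'->3', first base most significant.
// Reverse-complement collapsing maps every feature to the smaller of its id
// and the id of its reverse complement, so featurisation of a sequence and
// of its reverse complement coincide.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int base2i(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct KmerSpec {
  int l, k, npat, nword;
  bool collapse;
  std::vector<int> pat;     // npat * k informative positions (0-based)
  std::vector<int> rcpat;   // rc pattern index per pattern
  std::vector<int> rcword;  // reverse complement per k-mer word
  long long nfeat() const { return (long long)npat * nword; }
};

static KmerSpec make_spec(const IntegerMatrix& patterns,
                          const IntegerVector& rc_index, int l,
                          bool collapse) {
  KmerSpec s;
  s.l = l;
  s.k = patterns.nrow();
  s.npat = patterns.ncol();
  s.collapse = collapse;
  s.nword = 1;
  for (int i = 0; i < s.k; ++i) s.nword *= 4;
  s.pat.resize((size_t)s.npat * s.k);
  for (int j = 0; j < s.npat; ++j)
    for (int i = 0; i < s.k; ++i)
      s.pat[(size_t)j * s.k + i] = patterns(i, j);
  s.rcpat.assign(rc_index.begin(), rc_index.end());
  s.rcword.resize(s.nword);
  for (int w = 0; w < s.nword; ++w) {
    int rc = 0, x = w;
    for (int i = 0; i < s.k; ++i) {
      rc = (rc << 2) | (3 - (x & 3));
      x >>= 2;
    }
    s.rcword[w] = rc;
  }
  return s;
}

// invoke f(feature_id) for every (window, pattern) increment of seq
template <typename F>
static long long scan_seq(const std::string& seq, const KmerSpec& s, F f) {
  int n = (int)seq.size();
  if (n < s.l) return 0;
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base2i(seq[i]);
  // next_bad[i]: first index >= i with an invalid base (or n)
  std::vector<int> next_bad(n + 1);
  next_bad[n] = n + s.l;  // sentinel beyond any window
  for (int i = n - 1; i >= 0; --i)
    next_bad[i] = (code[i] < 0) ? i : next_bad[i + 1];
  long long n_windows = 0;
  for (int w = 0; w + s.l <= n; ++w) {
    if (next_bad[w] < w + s.l) continue;  // window contains N
    ++n_windows;
    for (int j = 0; j < s.npat; ++j) {
      int word = 0;
      const int* p = &s.pat[(size_t)j * s.k];
      for (int i = 0; i < s.k; ++i) word = (word << 2) | code[w + p[i]];
      long long id = (long long)j * s.nword + word;
      if (s.collapse) {
        long long alt = (long long)s.rcpat[j] * s.nword + s.rcword[word];
        if (alt < id) id = alt;
      }
      f(id);
    }
  }
  return n_windows;
}

// [[Rcpp::export]]
List cpp_kmer_featurize(std::string seq, IntegerMatrix patterns,
                        IntegerVector rc_index, int l, bool collapse) {
  KmerSpec s = make_spec(patterns, rc_index, l, collapse);
  std::vector<int> buf((size_t)s.nfeat(), 0);
  std::vector<long long> touched;
  long long nw = scan_seq(seq, s, [&](long long id) {
    if (buf[id]++ == 0) touched.push_back(id);
  });
  std::sort(touched.begin(), touched.end());
  IntegerVector ids(touched.size()), counts(touched.size());
  for (size_t i = 0; i < touched.size(); ++i) {
    ids[i] = (int)touched[i];
    counts[i] = buf[touched[i]];
  }
  return List::create(_["id"] = ids, _["count"] = counts,
                      _["n_windows"] = (double)nw);
}

// [[Rcpp::export]]
List cpp_kmer_class_stats(CharacterVector seqs, IntegerMatrix patterns,
                          IntegerVector rc_index, int l, bool collapse) {
  KmerSpec s = make_spec(patterns, rc_index, l, collapse);
  size_t nf = (size_t)s.nfeat();
  NumericVector sum(nf), sumsq(nf);
  std::vector<int> buf(nf, 0);
  std::vector<long long> touched;
  long long total_windows = 0;
  int n_used = 0;
  for (int si = 0; si < seqs.size(); ++si) {
    std::string seq = as<std::string>(seqs[si]);
    touched.clear();
    long long nw = scan_seq(seq, s, [&](long long id) {
      if (buf[id]++ == 0) touched.push_back(id);
    });
    total_windows += nw;
    if (nw > 0) ++n_used;
    for (long long id : touched) {
      double c = buf[id];
      sum[id] += c;
      sumsq[id] += c * c;
      buf[id] = 0;
    }
  }
  return List::create(_["sum"] = sum, _["sumsq"] = sumsq,
                      _["n_windows"] = (double)total_windows,
                      _["n_seq_used"] = n_used);
}

// [[Rcpp::export]]
NumericVector cpp_kmer_score(CharacterVector seqs, NumericVector w,
                             IntegerMatrix patterns, IntegerVector rc_index,
                             int l, bool collapse) {
  KmerSpec s = make_spec(patterns, rc_index, l, collapse);
  if ((long long)w.size() != s.nfeat())
    stop("weight vector length does not match the feature space");
  NumericVector out(seqs.size());
  for (int si = 0; si < seqs.size(); ++si) {
    std::string seq = as<std::string>(seqs[si]);
    double acc = 0.0;
    scan_seq(seq, s, [&](long long id) { acc += w[id]; });
    out[si] = acc;
  }
  return out;
}
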