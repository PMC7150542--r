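#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 0;  // N or anything else: no complement
  }
}

static std::string revcomp_checked(const std::string& s) {
  std::string r(s.size(), 0);
  for (size_t i = 0; i < s.size(); ++i) {
    char b = comp_base(s[s.size() - 1 - i]);
    if (!b) stop("sequence contains a character outside {A,C,G,T}");
    r[i] = b;
  }
  return r;
}

static inline std::string canonical_str(const std::string& s) {
  std::string rc = revcomp_checked(s);
  return (rc < s) ? rc : s;
}

// Positions i where seq[i] is not one of ACGT (uppercase) are "bad"; any
// window covering a bad position is skipped by every extractor below.
static std::vector<int> bad_prefix(const std::string& seq) {
  // prefix[i] = number of bad characters in seq[0..i-1]
  std::vector<int> prefix(seq.size() + 1, 0);
  for (size_t i = 0; i < seq.size(); ++i) {
    char c = seq[i];
    bool ok = (c == 'A' || c == 'C' || c == 'G' || c == 'T');
    prefix[i + 1] = prefix[i] + (ok ? 0 : 1);
  }
  return prefix;
}

static inline bool window_clean(const std::vector<int>& prefix, int start, int len) {
  return prefix[start + len] - prefix[start] == 0;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = canonical_str(s);
  }
  return out;
}

// Canonical k-mers of one sequence, one per clean window, in positional order.
// [[Rcpp::export]]
CharacterVector cpp_kmers(std::string seq, int k) {
  int L = (int)seq.size();
  std::vector<std::string> out;
  if (L >= k) {
    std::vector<int> prefix = bad_prefix(seq);
    for (int i = 0; i + k <= L; ++i) {
      if (!window_clean(prefix, i, k)) continue;
      out.push_back(canonical_str(seq.substr(i, k)));
    }
  }
  return wrap(out);
}

// Window minimizers of one sequence: for every clean k-length window, the
// lexicographically smallest canonical m-mer among its k-m+1 constituents.
// Returned as the (sorted) distinct set.
static std::vector<std::string> minimizers_one(const std::string& seq, int k, int m) {
  int L = (int)seq.size();
  std::unordered_set<std::string> res;
  if (L >= k) {
    std::vector<int> prefix = bad_prefix(seq);
    int nmm = L - m + 1;
    std::vector<std::string> cmm(nmm);
    std::vector<bool> have(nmm, false);
    for (int i = 0; i < nmm; ++i) {
      if (window_clean(prefix, i, m)) {
        cmm[i] = canonical_str(seq.substr(i, m));
        have[i] = true;
      }
    }
    for (int j = 0; j + k <= L; ++j) {
      if (!window_clean(prefix, j, k)) continue;
      const std::string* best = nullptr;
      for (int i = j; i <= j + k - m; ++i) {
        // clean k-window implies every m-window inside is clean
        if (!have[i]) continue;
        if (!best || cmm[i] < *best) best = &cmm[i];
      }
      if (best) res.insert(*best);
    }
  }
  std::vector<std::string> out(res.begin(), res.end());
  std::sort(out.begin(), out.end());
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_minimizers(std::string seq, int k, int m) {
  return wrap(minimizers_one(seq, k, m));
}

// Distinct seeds per read: canonical k-mer set (mode "kmer") or window
// minimizer set (mode "minimizer"). Distinctness is what edge weights count.
// [[Rcpp::export]]
List cpp_seed_sets(CharacterVector seqs, int k, int m, bool minimizer) {
  List out(seqs.size());
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    if (minimizer) {
      out[r] = wrap(minimizers_one(s, k, m));
    } else {
      int L = (int)s.size();
      std::unordered_set<std::string> set;
      if (L >= k) {
        std::vector<int> prefix = bad_prefix(s);
        for (int i = 0; i + k <= L; ++i) {
          if (!window_clean(prefix, i, k)) continue;
          set.insert(canonical_str(s.substr(i, k)));
        }
      }
      std::vector<std::string> v(set.begin(), set.end());
      std::sort(v.begin(), v.end());
      out[r] = wrap(v);
    }
  }
  return out;
}

// Occurrence counts of canonical k-mers pooled over `seqs`. If `subset` is
// given, only members of that set are counted (used to pull representative
// k-mer counts out of a whole sample cheaply). Names are sorted so output is
// deterministic.
// [[Rcpp::export]]
IntegerVector cpp_count_kmers(CharacterVector seqs, int k, Nullable<CharacterVector> subset = R_NilValue) {
  std::unordered_set<std::string> keep;
  bool filter = subset.isNotNull();
  if (filter) {
    CharacterVector sub(subset);
    for (R_xlen_t i = 0; i < sub.size(); ++i) keep.insert(as<std::string>(sub[i]));
  }
  std::unordered_map<std::string, int> counts;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    int L = (int)s.size();
    if (L < k) continue;
    std::vector<int> prefix = bad_prefix(s);
    for (int i = 0; i + k <= L; ++i) {
      if (!window_clean(prefix, i, k)) continue;
      std::string c = canonical_str(s.substr(i, k));
      if (filter && !keep.count(c)) continue;
      ++counts[c];
    }
  }
  std::vector<std::string> keys;
  keys.reserve(counts.size());
  for (auto& kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  IntegerVector out(keys.size());
  CharacterVector nm(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    out[i] = counts[keys[i]];
    nm[i] = keys[i];
  }
  out.attr("names") = nm;
  return out;
}

// Shared-seed pair counting without materializing the (seed, read) join in R.
// Takes the per-read distinct seed sets, drops seeds occurring in more than
// `max_seed_occurrence` reads (repeat mask) or fewer than 2, and counts, for
// every unordered read pair, the number of distinct shared surviving seeds.
// Returns pairs with count >= min_shared as a three-column data frame of
// 1-based read indices (i < j) and weights.
// [[Rcpp::export]]
DataFrame cpp_count_shared_seeds(List seed_sets, int max_seed_occurrence,
                                 int min_shared) {
  int n = seed_sets.size();
  std::unordered_map<std::string, std::vector<int> > by_seed;
  for (int r = 0; r < n; ++r) {
    CharacterVector s = seed_sets[r];
    for (R_xlen_t i = 0; i < s.size(); ++i)
      by_seed[as<std::string>(s[i])].push_back(r);
  }
  std::unordered_map<uint64_t, int> pair_count;
  for (auto& kv : by_seed) {
    std::vector<int>& rs = kv.second;
    int sz = (int)rs.size();
    if (sz < 2 || sz > max_seed_occurrence) continue;
    for (int a = 0; a < sz; ++a)
      for (int b = a + 1; b < sz; ++b) {
        uint64_t key = ((uint64_t)rs[a] << 32) | (uint64_t)rs[b];
        ++pair_count[key];
      }
  }
  std::vector<int> ii, jj, ww;
  for (auto& kv : pair_count) {
    if (kv.second < min_shared) continue;
    ii.push_back((int)(kv.first >> 32) + 1);
    jj.push_back((int)(kv.first & 0xffffffffu) + 1);
    ww.push_back(kv.second);
  }
  return DataFrame::create(Named("i") = ii, Named("j") = jj,
                           Named("weight") = ww);
}
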