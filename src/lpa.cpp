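#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Deterministic synchronous label propagation with damping.
//
// Nodes are 1..n (callers map tokens to indices in sorted token order, so the
// smallest integer label is also the lexicographically smallest token). Each
// node starts with its own label. Every sweep, all nodes simultaneously
// evaluate the total weight (or neighbour count if unweighted) of each label
// among their neighbours' previous-sweep labels — plus a self-stake for the
// node's current label equal to its strongest incident edge weight (1 when
// unweighted), which breaks the bipartite two-cycles synchronous LPA is
// otherwise prone to — and adopt the best candidate, ties broken by smallest
// label. Damping: a node switches only when the candidate strictly beats the
// score of its current label, or matches it with a smaller label id (so tie
// flips are monotone and cannot oscillate). Stops when a sweep changes
// nothing or after max_iters sweeps. No randomness: the result is schedule-
// and seed-independent.
// [[Rcpp::export]]
IntegerVector cpp_lpa(int n, IntegerVector from, IntegerVector to,
                      NumericVector weight, int max_iters, bool weighted) {
  std::vector<int> deg(n, 0);
  R_xlen_t m = from.size();
  for (R_xlen_t e = 0; e < m; ++e) {
    ++deg[from[e] - 1];
    ++deg[to[e] - 1];
  }
  std::vector<int> start(n + 1, 0);
  for (int v = 0; v < n; ++v) start[v + 1] = start[v] + deg[v];
  std::vector<int> adj(start[n]);
  std::vector<double> adjw(start[n]);
  std::vector<int> fill(n, 0);
  for (R_xlen_t e = 0; e < m; ++e) {
    int a = from[e] - 1, b = to[e] - 1;
    double w = weighted ? weight[e] : 1.0;
    adj[start[a] + fill[a]] = b; adjw[start[a] + fill[a]] = w; ++fill[a];
    adj[start[b] + fill[b]] = a; adjw[start[b] + fill[b]] = w; ++fill[b];
  }

  std::vector<int> label(n), next(n);
  for (int v = 0; v < n; ++v) label[v] = v;
  std::vector<double> self_w(n, 0.0);
  for (int v = 0; v < n; ++v)
    for (int p = start[v]; p < start[v + 1]; ++p)
      if (adjw[p] > self_w[v]) self_w[v] = adjw[p];

  std::unordered_map<int, double> acc;
  for (int t = 0; t < max_iters; ++t) {
    bool changed = false;
    for (int v = 0; v < n; ++v) {
      if (start[v + 1] == start[v]) { next[v] = label[v]; continue; }
      acc.clear();
      acc[label[v]] += self_w[v];
      for (int p = start[v]; p < start[v + 1]; ++p)
        acc[label[adj[p]]] += adjw[p];
      // deterministic argmax: sorted labels, first strict maximum
      std::vector<std::pair<int, double> > cand(acc.begin(), acc.end());
      std::sort(cand.begin(), cand.end(),
                [](const std::pair<int, double>& a, const std::pair<int, double>& b) {
                  return a.first < b.first;
                });
      int best = cand[0].first;
      double bw = cand[0].second;
      for (size_t i = 1; i < cand.size(); ++i)
        if (cand[i].second > bw) { best = cand[i].first; bw = cand[i].second; }
      double cur_w = acc.count(label[v]) ? acc[label[v]] : 0.0;
      bool adopt = (bw > cur_w) || (bw == cur_w && best < label[v]);
      next[v] = adopt ? best : label[v];
      if (next[v] != label[v]) changed = true;
    }
    label.swap(next);
    if (!changed) break;
  }

  IntegerVector out(n);
  for (int v = 0; v < n; ++v) out[v] = label[v] + 1;
  return out;
}
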