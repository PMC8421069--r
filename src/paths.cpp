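#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Median path length from query nodes to a terminal node set on a DAG.
//
// Edges are 0-based (from, to, length) and already oriented in the walking
// direction (the caller reverses them for upstream walks). For each query
// node the multiset of path lengths to the terminals is enumerated by DFS
// when the DP path count is at most max_paths; otherwise n_sample paths are
// drawn uniformly via the DP path-count weights and the median is estimated
// from the sample. Paths continue through terminals that have onward
// continuations (a terminal can be an interior node of a longer path).

static double median_of(std::vector<double> &x) {
  if (x.empty()) return NA_REAL;
  size_t n = x.size();
  std::sort(x.begin(), x.end());
  if (n % 2 == 1) return x[n / 2];
  return 0.5 * (x[n / 2 - 1] + x[n / 2]);
}

// [[Rcpp::export(name = ".path_length_medians")]]
List path_length_medians(int n_nodes, IntegerVector from, IntegerVector to,
                         NumericVector len, LogicalVector is_terminal,
                         IntegerVector queries, double max_paths,
                         int n_sample) {
  int ne = from.size();
  // adjacency
  std::vector<std::vector<int>> out(n_nodes);
  std::vector<int> indeg(n_nodes, 0);
  for (int e = 0; e < ne; ++e) {
    out[from[e]].push_back(e);
    indeg[to[e]]++;
  }
  // topological order (Kahn)
  std::vector<int> order;
  order.reserve(n_nodes);
  {
    std::vector<int> deg = indeg, stack;
    for (int v = 0; v < n_nodes; ++v)
      if (deg[v] == 0) stack.push_back(v);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      order.push_back(v);
      for (int e : out[v]) {
        if (--deg[to[e]] == 0) stack.push_back(to[e]);
      }
    }
    if ((int)order.size() != n_nodes) stop("edge set contains a cycle");
  }
  // path counts to terminals, walking along edges
  std::vector<double> cnt(n_nodes, 0.0);
  for (auto it = order.rbegin(); it != order.rend(); ++it) {
    int v = *it;
    if (is_terminal[v]) cnt[v] += 1.0;
    for (int e : out[v]) cnt[v] += cnt[to[e]];
  }

  int nq = queries.size();
  NumericVector med(nq), npaths(nq);
  LogicalVector sampled(nq);
  std::vector<double> lens;
  for (int qi = 0; qi < nq; ++qi) {
    int q = queries[qi];
    npaths[qi] = cnt[q];
    lens.clear();
    if (cnt[q] <= 0) {
      med[qi] = NA_REAL;
      sampled[qi] = false;
      continue;
    }
    if (cnt[q] <= max_paths) {
      // iterative DFS: stack of (node, accumulated length)
      std::vector<std::pair<int, double>> stack;
      stack.emplace_back(q, 0.0);
      while (!stack.empty()) {
        auto s = stack.back();
        stack.pop_back();
        if (is_terminal[s.first]) lens.push_back(s.second);
        for (int e : out[s.first]) {
          if (cnt[to[e]] > 0 || is_terminal[to[e]])
            stack.emplace_back(to[e], s.second + len[e]);
        }
      }
      sampled[qi] = false;
    } else {
      lens.reserve(n_sample);
      for (int k = 0; k < n_sample; ++k) {
        int cur = q;
        double acc = 0.0;
        for (;;) {
          double w_here = is_terminal[cur] ? 1.0 : 0.0;
          double u = unif_rand() * cnt[cur];
          if (u < w_here) break;
          double running = w_here;
          int chosen = -1;
          for (int e : out[cur]) {
            running += cnt[to[e]];
            if (u < running) {
              chosen = e;
              break;
            }
          }
          if (chosen < 0) break; // numerical guard
          acc += len[chosen];
          cur = to[chosen];
        }
        lens.push_back(acc);
      }
      sampled[qi] = true;
    }
    med[qi] = median_of(lens);
  }
  return List::create(_["median"] = med, _["n_paths"] = npaths,
                      _["sampled"] = sampled);
}
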