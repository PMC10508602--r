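#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Uniform index on 0..n-1 from R's RNG stream (caller must hold RNGScope,
// which Rcpp attributes provide automatically).
static inline int runif_index(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// One complete pass of the urn process: every node decides exactly once.
//
// Decision rule per event, matching the printed algorithm:
//  * draw an undecided node l uniformly among those whose local urn is
//    non-empty (rejection-resampling of l is equivalent to this uniform draw);
//  * draw a decided neighbour k uniformly from l's deduplicated local urn;
//  * with prob ps copy k's colour; otherwise with prob pc adopt the purpose
//    of a uniformly drawn hyperedge containing l; otherwise pick RED with
//    prob qs.
//  * if NO undecided node has a decided neighbour, draw l uniformly among
//    all undecided and use the non-social branch (pc purpose, else qs).
//
// edges: list of IntegerVector (1-based node ids); node_edges: per-node
// 1-based hyperedge ids; purpose_red: per-edge flag; seed_nodes get colours
// first n_seed_red RED then BLUE, all at step 0.
// Colours: 1 = RED, 2 = BLUE. Returns decision order, colours and steps.
// [[Rcpp::export(name = ".urn_engine")]]
List urn_engine(int m, List edges, List node_edges, LogicalVector purpose_red,
                double ps, double pc, double qs,
                IntegerVector seed_nodes, int n_seed_red) {
  int ne = edges.size();
  std::vector< std::vector<int> > ed(ne), ned(m), ed_dec(ne);
  for (int e = 0; e < ne; ++e) {
    IntegerVector v = edges[e];
    ed[e].assign(v.begin(), v.end());
    ed_dec[e].reserve(v.size());
  }
  for (int i = 0; i < m; ++i) {
    IntegerVector v = node_edges[i];
    ned[i].reserve(v.size());
    for (R_xlen_t j = 0; j < v.size(); ++j) ned[i].push_back(v[j] - 1);
  }

  std::vector<char> color(m + 1, 0), elig(m + 1, 0), in_union(m + 1, 0);
  std::vector<int> undecided(m), pos(m + 1), cand, uni;
  cand.reserve(m); uni.reserve(m);
  for (int i = 0; i < m; ++i) { undecided[i] = i + 1; pos[i + 1] = i; }
  int n_undec = m, n_out = 0;
  IntegerVector out_node(m), out_color(m), out_step(m);

  // commit a decision: record, remove l from the undecided pool, push l into
  // the decided list of each of its hyperedges, flag new eligible nodes
  auto commit = [&](int l, int col, int step) {
    color[l] = (char)col;
    out_node[n_out] = l; out_color[n_out] = col; out_step[n_out] = step;
    ++n_out;
    int p = pos[l], last = undecided[n_undec - 1];
    undecided[p] = last; pos[last] = p; --n_undec;
    const std::vector<int>& hes = ned[l - 1];
    for (size_t a = 0; a < hes.size(); ++a) {
      int e = hes[a];
      ed_dec[e].push_back(l);
      if (ed_dec[e].size() == 1)
        for (size_t b = 0; b < ed[e].size(); ++b) elig[ed[e][b]] = 1;
    }
  };

  int ns = seed_nodes.size();
  for (int i = 0; i < ns; ++i)
    commit(seed_nodes[i], i < n_seed_red ? 1 : 2, 0);

  int step = 0;
  while (n_undec > 0) {
    ++step;
    cand.clear();
    for (int i = 0; i < n_undec; ++i)
      if (elig[undecided[i]]) cand.push_back(undecided[i]);
    int l, col;
    if (!cand.empty()) {
      l = cand[runif_index((int)cand.size())];
      const std::vector<int>& hes = ned[l - 1];
      int k;
      if (hes.size() == 1) {
        const std::vector<int>& dm = ed_dec[hes[0]];
        k = dm[runif_index((int)dm.size())];
      } else {
        uni.clear();
        for (size_t a = 0; a < hes.size(); ++a) {
          const std::vector<int>& dm = ed_dec[hes[a]];
          for (size_t b = 0; b < dm.size(); ++b)
            if (!in_union[dm[b]]) { in_union[dm[b]] = 1; uni.push_back(dm[b]); }
        }
        k = uni[runif_index((int)uni.size())];
        for (size_t a = 0; a < uni.size(); ++a) in_union[uni[a]] = 0;
      }
      if (unif_rand() <= ps) {
        col = color[k];
      } else if (unif_rand() < pc) {
        int e = hes.size() == 1 ? hes[0] : hes[runif_index((int)hes.size())];
        col = purpose_red[e] ? 1 : 2;
      } else {
        col = unif_rand() <= qs ? 1 : 2;
      }
    } else {
      l = undecided[runif_index(n_undec)];
      const std::vector<int>& hes = ned[l - 1];
      if (!hes.empty() && unif_rand() < pc) {
        int e = hes.size() == 1 ? hes[0] : hes[runif_index((int)hes.size())];
        col = purpose_red[e] ? 1 : 2;
      } else {
        col = unif_rand() <= qs ? 1 : 2;
      }
    }
    commit(l, col, step);
  }
  return List::create(_["node"] = out_node, _["color"] = out_color,
                      _["step"] = out_step);
}
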