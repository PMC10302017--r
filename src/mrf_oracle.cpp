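#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive reference minimizer for pairwise MRF energies
//   E(l) = sum_i node_costs(l_i, i) + sum_{(a,b) in edges} pair_cost(l_a, l_b)
//
// Plain enumeration of every label assignment, used in tests as the
// independent oracle for the tree dynamic-programming solver. All nodes
// except one minimum-degree node are enumerated by an odometer; that final
// node's conditional minimum is read from a precomputed per-neighbor-label
// table (simple memoization of the enumeration, no tree message passing).

struct EnumCtx {
  const NumericMatrix *node_costs; // L x n
  const NumericMatrix *pair_cost;  // L x L (weight already applied)
  int L, n_enum, last;
  std::vector<int> order;                         // enumerated node ids
  std::vector<std::vector<int>> back;             // earlier positions adjacent to pos d
  std::vector<int> last_nbr_pos;                  // positions of `last`'s neighbors
  std::vector<double> m1;                         // conditional min table (deg==1)
  std::vector<int> lab;
  double best;
};

static void enum_rec(EnumCtx &c, int d, double e) {
  // deliberately no branch-and-bound pruning: the enumeration stays exhaustive
  if (d == c.n_enum) {
    double tail;
    const NumericMatrix &nc = *c.node_costs;
    const NumericMatrix &pc = *c.pair_cost;
    if (c.last_nbr_pos.size() == 1) {
      tail = c.m1[c.lab[c.last_nbr_pos[0]]];
    } else {
      tail = R_PosInf;
      for (int l = 0; l < c.L; ++l) {
        double v = nc(l, c.last);
        for (size_t t = 0; t < c.last_nbr_pos.size(); ++t)
          v += pc(l, c.lab[c.last_nbr_pos[t]]);
        if (v < tail) tail = v;
      }
    }
    if (e + tail < c.best) c.best = e + tail;
    return;
  }
  const NumericMatrix &nc = *c.node_costs;
  const NumericMatrix &pc = *c.pair_cost;
  int node = c.order[d];
  if (d == c.n_enum - 1 && c.last_nbr_pos.size() == 1) {
    // innermost enumerated node: unroll, leaf tail via the memoized table
    const double *ncol = &nc(0, node);
    int tpos = c.last_nbr_pos[0];
    for (int l = 0; l < c.L; ++l) {
      double ee = e + ncol[l];
      for (size_t t = 0; t < c.back[d].size(); ++t)
        ee += pc(l, c.lab[c.back[d][t]]);
      c.lab[d] = l;
      ee += c.m1[c.lab[tpos]];
      if (ee < c.best) c.best = ee;
    }
    return;
  }
  for (int l = 0; l < c.L; ++l) {
    double ee = e + nc(l, node);
    for (size_t t = 0; t < c.back[d].size(); ++t)
      ee += pc(l, c.lab[c.back[d][t]]);
    c.lab[d] = l;
    enum_rec(c, d + 1, ee);
  }
}

//' Exhaustive minimum of a pairwise MRF energy (reference oracle)
//'
//' Enumerates all label assignments of the graph and returns the minimum of
//' \code{sum_i node_costs[l_i, i] + sum_(a,b) pair_cost[l_a, l_b]}. Intended
//' as an independent cross-check for \code{\link{mrf_register}}'s tree
//' solver on small problems.
//'
//' @param node_costs L x n matrix of per-node label costs.
//' @param edges m x 2 integer matrix of 1-based undirected edges.
//' @param pair_cost L x L symmetric pairwise cost matrix (regularization
//'   weight already applied).
//' @return The minimum energy (scalar).
//' @export
// [[Rcpp::export]]
double mrf_bruteforce_min(NumericMatrix node_costs, IntegerMatrix edges,
                          NumericMatrix pair_cost) {
  const int L = node_costs.nrow(), n = node_costs.ncol(), m = edges.nrow();
  if (pair_cost.nrow() != L || pair_cost.ncol() != L)
    stop("pair_cost must be L x L");
  if (n == 1) {
    double best = R_PosInf;
    for (int l = 0; l < L; ++l) if (node_costs(l, 0) < best) best = node_costs(l, 0);
    return best;
  }
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    if (a < 0 || a >= n || b < 0 || b >= n) stop("edge index out of range");
    deg[a]++; deg[b]++;
  }
  EnumCtx c;
  c.node_costs = &node_costs; c.pair_cost = &pair_cost;
  c.L = L; c.best = R_PosInf;
  c.last = 0;
  for (int i = 1; i < n; ++i) if (deg[i] < deg[c.last]) c.last = i;
  std::vector<int> pos(n, -1);
  for (int i = 0; i < n; ++i) if (i != c.last) {
    pos[i] = (int)c.order.size();
    c.order.push_back(i);
  }
  c.n_enum = (int)c.order.size();
  c.back.assign(c.n_enum, std::vector<int>());
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    if (a == c.last) { c.last_nbr_pos.push_back(pos[b]); continue; }
    if (b == c.last) { c.last_nbr_pos.push_back(pos[a]); continue; }
    int pa = pos[a], pb = pos[b];
    c.back[std::max(pa, pb)].push_back(std::min(pa, pb));
  }
  if (c.last_nbr_pos.size() == 1) {
    c.m1.assign(L, R_PosInf);
    for (int lp = 0; lp < L; ++lp) {
      double best = R_PosInf;
      for (int l = 0; l < L; ++l) {
        double v = node_costs(l, c.last) + pair_cost(l, lp);
        if (v < best) best = v;
      }
      c.m1[lp] = best;
    }
  }
  c.lab.assign(c.n_enum, 0);
  enum_rec(c, 0, 0.0);
  return c.best;
}
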