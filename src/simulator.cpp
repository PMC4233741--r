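#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Birth-death Moran process on a graph in CSR adjacency form.
// Each elementary event: pick a reproducing node fitness-proportionally
// (mutants have fitness r), then replace a uniformly chosen neighbour with
// its offspring. Every event counts one time step, including events that
// do not change the configuration, so step counts match the discrete-time
// chain solved exactly elsewhere in the package.
//
// Constant work per step: the mutant and wild-type node sets are kept as
// swap-delete lists with position indices, so fitness-class sampling and
// membership updates are O(1).

// [[Rcpp::export]]
List sim_moran_cpp(IntegerVector adj, IntegerVector adj_start, double r,
                   IntegerVector start_nodes) {
  const int n = adj_start.size() - 1;
  const int reps = start_nodes.size();
  LogicalVector fixed(reps);
  NumericVector steps(reps);

  std::vector<char> is_mut(n);
  std::vector<int> mut(n), wild(n), pos(n);

  for (int rep = 0; rep < reps; ++rep) {
    std::fill(is_mut.begin(), is_mut.end(), 0);
    int m = 1;
    const int s0 = start_nodes[rep];
    is_mut[s0] = 1;
    mut[0] = s0;
    pos[s0] = 0;
    int nw = 0;
    for (int v = 0; v < n; ++v) {
      if (v != s0) { wild[nw] = v; pos[v] = nw; ++nw; }
    }
    double t = 0.0;
    while (m > 0 && m < n) {
      t += 1.0;
      const double W = r * m + (n - m);
      int birth;
      if (unif_rand() * W < r * m) {
        birth = mut[(int)(unif_rand() * m)];
      } else {
        birth = wild[(int)(unif_rand() * nw)];
      }
      const int d = adj_start[birth + 1] - adj_start[birth];
      const int target = adj[adj_start[birth] + (int)(unif_rand() * d)];
      if (is_mut[target] != is_mut[birth]) {
        if (is_mut[target]) {
          // mutant replaced by wild-type offspring
          const int p = pos[target];
          mut[p] = mut[m - 1];
          pos[mut[p]] = p;
          --m;
          is_mut[target] = 0;
          wild[nw] = target;
          pos[target] = nw;
          ++nw;
        } else {
          const int p = pos[target];
          wild[p] = wild[nw - 1];
          pos[wild[p]] = p;
          --nw;
          is_mut[target] = 1;
          mut[m] = target;
          pos[target] = m;
          ++m;
        }
      }
    }
    fixed[rep] = (m == n);
    steps[rep] = t;
  }
  return List::create(_["fixed"] = fixed, _["steps"] = steps);
}
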