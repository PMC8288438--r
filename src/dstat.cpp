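#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Tree encoding shared with R (see tree_encoding() in R/dstat.R):
//  ord     - internal node ids (1-based, ape numbering) ordered children-first
//  child1/child2 - for each node id, its two children (0 for tips)
// Nodal value of an internal node is the unweighted mean of its two children;
// d is the sum over all edges of |parent value - child value|.

static double d_from_tips(const IntegerVector& ord, const IntegerVector& child1,
                          const IntegerVector& child2, std::vector<double>& val) {
  double d = 0.0;
  const int m = ord.size();
  for (int i = 0; i < m; ++i) {
    const int v = ord[i] - 1;
    const int a = child1[v] - 1;
    const int b = child2[v] - 1;
    const double mu = 0.5 * (val[a] + val[b]);
    val[v] = mu;
    d += std::fabs(mu - val[a]) + std::fabs(mu - val[b]);
  }
  return d;
}

// [[Rcpp::export]]
double cpp_d_value(IntegerVector ord, IntegerVector child1, IntegerVector child2,
                   NumericVector x, int n_nodes) {
  std::vector<double> val(n_nodes, 0.0);
  for (int i = 0; i < x.size(); ++i) val[i] = x[i];
  return d_from_tips(ord, child1, child2, val);
}

// d for every column of a 0/1 tip-state matrix (n_tips x B)
// [[Rcpp::export]]
NumericVector cpp_d_columns(IntegerVector ord, IntegerVector child1, IntegerVector child2,
                            IntegerMatrix states, int n_nodes) {
  const int B = states.ncol(), n = states.nrow();
  NumericVector out(B);
  std::vector<double> val(n_nodes);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) val[i] = states(i, b);
    out[b] = d_from_tips(ord, child1, child2, val);
  }
  return out;
}

// Tip-shuffling null: B uniform permutations of the tip values (prevalence
// preserved exactly). Uses R's RNG so results are seed-reproducible.
// [[Rcpp::export]]
NumericVector cpp_random_null(IntegerVector ord, IntegerVector child1, IntegerVector child2,
                              NumericVector x, int n_nodes, int B) {
  const int n = x.size();
  NumericVector out(B);
  std::vector<double> val(n_nodes);
  for (int b = 0; b < B; ++b) {
    IntegerVector perm = sample(n, n, false); // 1-based
    for (int i = 0; i < n; ++i) val[i] = x[perm[i] - 1];
    out[b] = d_from_tips(ord, child1, child2, val);
  }
  return out;
}

// One threshold-Brownian draw: accumulate N(0, edge length) increments from a
// root value of 0 along the preorder edge list, then mark the k highest-valued
// tips present. Ties (possible with zero-length edges) are broken by a seeded
// uniform draw per tip so the result is deterministic given the RNG state.
static void bm_draw(const IntegerVector& pre_parent, const IntegerVector& pre_child,
                    const NumericVector& elen, int root, int n_tips, int k,
                    std::vector<double>& val, std::vector<double>& u,
                    std::vector<int>& idx, int* present) {
  val[root - 1] = 0.0;
  const int ne = pre_parent.size();
  for (int e = 0; e < ne; ++e)
    val[pre_child[e] - 1] = val[pre_parent[e] - 1] + norm_rand() * std::sqrt(elen[e]);
  for (int i = 0; i < n_tips; ++i) { u[i] = unif_rand(); idx[i] = i; }
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (val[a] != val[b]) return val[a] > val[b];
    return u[a] > u[b];
  });
  for (int i = 0; i < n_tips; ++i) present[i] = 0;
  for (int i = 0; i < k; ++i) present[idx[i]] = 1;
}

// B binary tip-state draws from the threshold-Brownian model (n_tips x B).
// This is the single shared code path behind both the Brownian null and the
// synthetic-data brownian_threshold regime.
// [[Rcpp::export]]
IntegerMatrix cpp_bm_states(IntegerVector pre_parent, IntegerVector pre_child,
                            NumericVector elen, int root, int n_tips, int n_nodes,
                            int k, int B) {
  IntegerMatrix out(n_tips, B);
  std::vector<double> val(n_nodes), u(n_tips);
  std::vector<int> idx(n_tips), present(n_tips);
  for (int b = 0; b < B; ++b) {
    bm_draw(pre_parent, pre_child, elen, root, n_tips, k, val, u, idx, present.data());
    for (int i = 0; i < n_tips; ++i) out(i, b) = present[i];
  }
  return out;
}

// Brownian-threshold null distribution of d. Consumes the identical RNG
// stream as cpp_bm_states for the same number of replicates.
// [[Rcpp::export]]
NumericVector cpp_brownian_null(IntegerVector ord, IntegerVector child1, IntegerVector child2,
                                IntegerVector pre_parent, IntegerVector pre_child,
                                NumericVector elen, int root, int n_tips, int n_nodes,
                                int k, int B) {
  NumericVector out(B);
  std::vector<double> val(n_nodes), bmval(n_nodes), u(n_tips);
  std::vector<int> idx(n_tips), present(n_tips);
  for (int b = 0; b < B; ++b) {
    bm_draw(pre_parent, pre_child, elen, root, n_tips, k, bmval, u, idx, present.data());
    for (int i = 0; i < n_tips; ++i) val[i] = present[i];
    out[b] = d_from_tips(ord, child1, child2, val);
  }
  return out;
}
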