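#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving; small fixed arrays reused across realizations.
static inline int uf_find(std::vector<int> &par, int x) {
  while (par[x] != x) {
    par[x] = par[par[x]];
    x = par[x];
  }
  return x;
}

static inline void uf_union(std::vector<int> &par, int a, int b) {
  int ra = uf_find(par, a), rb = uf_find(par, b);
  if (ra != rb) par[rb] = ra;
}

//' @name mc_connectivity_counts
//' @noRd
// [[Rcpp::export]]
NumericMatrix mc_connectivity_counts(int n_vertices, IntegerMatrix edges,
                                     NumericVector probs, int n_samples) {
  const int m = edges.nrow();
  NumericMatrix counts(n_vertices, n_vertices);
  std::vector<int> par(n_vertices);
  std::vector<int> root(n_vertices);
  RNGScope scope; // uses R's RNG: reproducible under set.seed()
  for (int s = 0; s < n_samples; ++s) {
    for (int v = 0; v < n_vertices; ++v) par[v] = v;
    for (int e = 0; e < m; ++e) {
      if (unif_rand() < probs[e]) uf_union(par, edges(e, 0), edges(e, 1));
    }
    for (int v = 0; v < n_vertices; ++v) root[v] = uf_find(par, v);
    for (int i = 0; i < n_vertices; ++i) {
      const int ri = root[i];
      for (int j = i + 1; j < n_vertices; ++j) {
        if (ri == root[j]) {
          counts(i, j) += 1.0;
        }
      }
    }
  }
  // symmetrize
  for (int i = 0; i < n_vertices; ++i)
    for (int j = i + 1; j < n_vertices; ++j) counts(j, i) = counts(i, j);
  return counts;
}

//' @name exact_connectivity_cpp
//' @noRd
// [[Rcpp::export]]
NumericMatrix exact_connectivity_cpp(int n_vertices, IntegerMatrix edges,
                                     NumericVector probs) {
  const int m = edges.nrow();
  if (m > 25) stop("exact enumeration limited to 25 edges");
  NumericMatrix acc(n_vertices, n_vertices);
  std::vector<int> par(n_vertices);
  std::vector<int> root(n_vertices);
  const long long nsub = 1LL << m;
  for (long long mask = 0; mask < nsub; ++mask) {
    double pr = 1.0;
    for (int v = 0; v < n_vertices; ++v) par[v] = v;
    for (int e = 0; e < m; ++e) {
      if (mask & (1LL << e)) {
        pr *= probs[e];
        uf_union(par, edges(e, 0), edges(e, 1));
      } else {
        pr *= (1.0 - probs[e]);
      }
    }
    if (pr == 0.0) continue;
    for (int v = 0; v < n_vertices; ++v) root[v] = uf_find(par, v);
    for (int i = 0; i < n_vertices; ++i) {
      const int ri = root[i];
      for (int j = i + 1; j < n_vertices; ++j) {
        if (ri == root[j]) acc(i, j) += pr;
      }
    }
  }
  for (int i = 0; i < n_vertices; ++i) {
    acc(i, i) = 1.0;
    for (int j = i + 1; j < n_vertices; ++j) acc(j, i) = acc(i, j);
  }
  return acc;
}
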