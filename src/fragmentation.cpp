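#include <Rcpp.h>
using namespace Rcpp;

// Disjoint-set forest with union by size and path halving.
// Tracks T = sum over components of n_i * log(n_i); singletons contribute 0,
// so nodes not yet re-inserted (i.e. still "isolated") need no bookkeeping.
struct DSF {
  std::vector<int> parent;
  std::vector<int> size;
  double T;
  explicit DSF(int n) : parent(n), size(n, 1), T(0.0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    double sa = size[a], sb = size[b];
    T += (sa + sb) * std::log(sa + sb);
    if (sa > 1.0) T -= sa * std::log(sa);
    if (sb > 1.0) T -= sb * std::log(sb);
    parent[b] = a;
    size[a] += size[b];
  }
};

// Compressed sparse adjacency built once per curve; edges are 1-based vertex ids.
static void build_csr(const IntegerVector& from, const IntegerVector& to, int n,
                      std::vector<int>& off, std::vector<int>& adj) {
  R_xlen_t m = from.size();
  off.assign((size_t)n + 2, 0);
  for (R_xlen_t e = 0; e < m; ++e) {
    off[(size_t)from[e] + 1]++;
    off[(size_t)to[e] + 1]++;
  }
  for (size_t i = 1; i < off.size(); ++i) off[i] += off[i - 1];
  adj.resize(2 * (size_t)m);
  std::vector<int> cur(off.begin(), off.end() - 1);
  for (R_xlen_t e = 0; e < m; ++e) {
    int u = from[e], v = to[e];
    adj[(size_t)cur[u]++] = v;
    adj[(size_t)cur[v]++] = u;
  }
}

//' @title Fragmentation-entropy curve along a removal order (internal)
//' @description For k = 0..n removed nodes, the normalized Shannon entropy of
//'   component sizes, where removal isolates a node (deletes its incident
//'   edges, keeps it as a size-1 component) and the denominator N stays the
//'   original node count. Computed by re-inserting nodes in reverse order with
//'   incremental component merging, O((N+E) alpha).
//' @param from,to integer endpoints (1-based) of each undirected edge
//' @param order integer permutation of 1..n, the removal order
//' @param n total node count
//' @return numeric vector of length n+1: S at f = k/n for k = 0..n
//' @keywords internal
// [[Rcpp::export]]
NumericVector frag_curve_cpp(IntegerVector from, IntegerVector to,
                             IntegerVector order, int n) {
  if (n < 2) stop("entropy normalization requires n >= 2");
  if (order.size() != n) stop("removal order must cover all nodes");
  std::vector<int> off, adj;
  build_csr(from, to, n, off, adj);

  std::vector<char> present((size_t)n + 1, 0);
  DSF dsf(n + 1);
  NumericVector S(n + 1);
  const double denom = (double)n * std::log((double)n);

  S[n] = 1.0;  // all nodes isolated
  // re-insert nodes order[n-1], order[n-2], ...; after inserting the node at
  // position k (0-based) of the reversed order, k+1 nodes are present and
  // n-(k+1) removed.
  for (int k = n - 1; k >= 1; --k) {
    int v = order[k];
    present[(size_t)v] = 1;
    for (int a = off[(size_t)v]; a < off[(size_t)v + 1]; ++a) {
      int u = adj[(size_t)a];
      if (present[(size_t)u]) dsf.unite(v, u);
    }
    S[k] = 1.0 - dsf.T / denom;
  }
  {
    int v = order[0];
    present[(size_t)v] = 1;
    for (int a = off[(size_t)v]; a < off[(size_t)v + 1]; ++a) {
      int u = adj[(size_t)a];
      if (present[(size_t)u]) dsf.unite(v, u);
    }
    S[0] = 1.0 - dsf.T / denom;
  }
  return S;
}

//' @title Adaptive max-degree removal order (internal)
//' @description Repeatedly removes the node with the highest current degree
//'   (degrees recomputed as removal proceeds), ties broken by the supplied
//'   random permutation. Bucket queue with lazy deletion, O(N + E).
//' @param from,to integer endpoints (1-based) of each undirected edge
//' @param perm integer permutation of 1..n fixing the tie order
//' @param n total node count
//' @return integer removal order (1-based vertex ids)
//' @keywords internal
// [[Rcpp::export]]
IntegerVector adaptive_degree_order_cpp(IntegerVector from, IntegerVector to,
                                        IntegerVector perm, int n) {
  std::vector<int> off, adj;
  build_csr(from, to, n, off, adj);
  std::vector<int> deg((size_t)n + 1, 0);
  int maxd = 0;
  for (int v = 1; v <= n; ++v) {
    deg[(size_t)v] = off[(size_t)v + 1] - off[(size_t)v];
    if (deg[(size_t)v] > maxd) maxd = deg[(size_t)v];
  }
  std::vector<std::vector<int> > bucket((size_t)maxd + 1);
  std::vector<size_t> head((size_t)maxd + 1, 0);
  for (R_xlen_t i = 0; i < perm.size(); ++i) {
    bucket[(size_t)deg[(size_t)perm[i]]].push_back(perm[i]);
  }
  std::vector<char> removed((size_t)n + 1, 0);
  IntegerVector out(n);
  int cur = maxd, filled = 0;
  while (filled < n) {
    int v = -1;
    while (cur >= 0) {
      if (head[(size_t)cur] >= bucket[(size_t)cur].size()) {
        if (cur == 0) break;
        --cur;
        continue;
      }
      int cand = bucket[(size_t)cur][head[(size_t)cur]++];
      if (!removed[(size_t)cand] && deg[(size_t)cand] == cur) { v = cand; break; }
    }
    if (v < 0) stop("internal error: bucket queue exhausted early");
    removed[(size_t)v] = 1;
    out[filled++] = v;
    for (int a = off[(size_t)v]; a < off[(size_t)v + 1]; ++a) {
      int u = adj[(size_t)a];
      if (!removed[(size_t)u]) {
        int d = --deg[(size_t)u];
        bucket[(size_t)d].push_back(u);
        if (d > cur) cur = d;
      }
    }
  }
  return out;
}

//' @title Greedy node+first-neighbor removal grouping (internal)
//' @description Walks a priority order; each not-yet-removed node is taken
//'   together with its still-remaining neighbors as one removal step.
//' @param from,to integer endpoints (1-based) of each undirected edge
//' @param priority integer permutation of 1..n (highest priority first)
//' @param n total node count
//' @return list(order = concatenated removal order, group_sizes = nodes per step)
//' @keywords internal
// [[Rcpp::export]]
List neighborhood_groups_cpp(IntegerVector from, IntegerVector to,
                             IntegerVector priority, int n) {
  std::vector<int> off, adj;
  build_csr(from, to, n, off, adj);
  std::vector<char> removed((size_t)n + 1, 0);
  std::vector<int> order;
  order.reserve(n);
  std::vector<int> gsizes;
  for (R_xlen_t i = 0; i < priority.size(); ++i) {
    int v = priority[i];
    if (removed[(size_t)v]) continue;
    int start = (int)order.size();
    removed[(size_t)v] = 1;
    order.push_back(v);
    for (int a = off[(size_t)v]; a < off[(size_t)v + 1]; ++a) {
      int u = adj[(size_t)a];
      if (!removed[(size_t)u]) {
        removed[(size_t)u] = 1;
        order.push_back(u);
      }
    }
    gsizes.push_back((int)order.size() - start);
  }
  return List::create(_["order"] = wrap(order), _["group_sizes"] = wrap(gsizes));
}
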