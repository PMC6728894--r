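#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Adjacency lists from a dense 0/1 matrix (assumed validated in R:
// symmetric, zero diagonal).
static std::vector<std::vector<int>> adj_list(const IntegerMatrix& a) {
  int n = a.nrow();
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (a(i, j) != 0 && i != j) nb[i].push_back(j);
  return nb;
}

// BFS from every node; -1 marks unreachable pairs.
// [[Rcpp::export(name = ".bfs_distances_cpp")]]
IntegerMatrix bfs_distances_cpp(const IntegerMatrix& adjacency) {
  int n = adjacency.nrow();
  std::vector<std::vector<int>> nb = adj_list(adjacency);
  IntegerMatrix d(n, n);
  std::fill(d.begin(), d.end(), -1);
  std::vector<int> q(n);
  for (int s = 0; s < n; ++s) {
    int head = 0, tail = 0;
    d(s, s) = 0;
    q[tail++] = s;
    while (head < tail) {
      int u = q[head++];
      int du = d(u, s);
      for (int v : nb[u]) {
        if (d(v, s) < 0) {
          d(v, s) = du + 1;
          q[tail++] = v;
        }
      }
    }
  }
  return d;
}

// Per-node clustering: triangles through i over Di*(Di-1)/2, zero when Di < 2.
// [[Rcpp::export(name = ".clustering_cpp")]]
NumericVector clustering_cpp(const IntegerMatrix& adjacency) {
  int n = adjacency.nrow();
  std::vector<std::vector<int>> nb = adj_list(adjacency);
  NumericVector c(n);
  for (int i = 0; i < n; ++i) {
    int k = nb[i].size();
    if (k < 2) { c[i] = 0.0; continue; }
    long links = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (adjacency(nb[i][a], nb[i][b]) != 0) ++links;
    c[i] = (2.0 * links) / (double)(k * (k - 1));
  }
  return c;
}

// Fast path for null ensembles: mean clustering, finite-pair mean path
// length, and the count of disconnected (unordered) pairs in one pass.
// [[Rcpp::export(name = ".cp_lp_cpp")]]
NumericVector cp_lp_cpp(const IntegerMatrix& adjacency) {
  int n = adjacency.nrow();
  NumericVector cl = clustering_cpp(adjacency);
  double cp = 0.0;
  for (int i = 0; i < n; ++i) cp += cl[i];
  cp /= n;

  std::vector<std::vector<int>> nb = adj_list(adjacency);
  double sum = 0.0;
  long finite = 0, inf_pairs = 0;
  std::vector<int> dist(n), q(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    dist[s] = 0; q[tail++] = s;
    while (head < tail) {
      int u = q[head++];
      for (int v : nb[u])
        if (dist[v] < 0) { dist[v] = dist[u] + 1; q[tail++] = v; }
    }
    for (int t = s + 1; t < n; ++t) {
      if (dist[t] > 0) { sum += dist[t]; ++finite; }
      else if (dist[t] < 0) ++inf_pairs;
    }
  }
  double lp = finite > 0 ? sum / finite : R_PosInf;
  return NumericVector::create(cp, lp, (double)inf_pairs);
}

// Nodal efficiency of the subgraph induced by each node's neighbors
// (global efficiency of G_i); nodes with fewer than 2 neighbors score 0.
// [[Rcpp::export(name = ".local_efficiency_cpp")]]
NumericVector local_efficiency_cpp(const IntegerMatrix& adjacency) {
  int n = adjacency.nrow();
  std::vector<std::vector<int>> nb = adj_list(adjacency);
  NumericVector e(n);
  for (int i = 0; i < n; ++i) {
    int m = nb[i].size();
    if (m < 2) { e[i] = 0.0; continue; }
    // BFS within the induced subgraph on nb[i]
    std::vector<int> idx(n, -1);
    for (int a = 0; a < m; ++a) idx[nb[i][a]] = a;
    double acc = 0.0;
    std::vector<int> dist(m), q(m);
    for (int s = 0; s < m; ++s) {
      std::fill(dist.begin(), dist.end(), -1);
      int head = 0, tail = 0;
      dist[s] = 0; q[tail++] = s;
      while (head < tail) {
        int u = q[head++];
        for (int w : nb[nb[i][u]]) {
          int v = idx[w];
          if (v >= 0 && dist[v] < 0) { dist[v] = dist[u] + 1; q[tail++] = v; }
        }
      }
      for (int t = 0; t < m; ++t)
        if (t != s && dist[t] > 0) acc += 1.0 / dist[t];
    }
    e[i] = acc / ((double)m * (m - 1));
  }
  return e;
}

// Degree-preserving double-edge swaps (Maslov-Sneppen). Each trial picks
// two edges (a,b), (c,d) with R's RNG and proposes (a,d), (c,b); rejected
// if the four endpoints are not distinct or either new edge exists.
// Returns the rewired adjacency plus the number of accepted swaps.
// [[Rcpp::export(name = ".rewire_cpp")]]
List rewire_cpp(const IntegerMatrix& adjacency, int n_trials) {
  int n = adjacency.nrow();
  IntegerMatrix a = clone(adjacency);
  std::vector<int> eu, ev;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (a(i, j) != 0) { eu.push_back(i); ev.push_back(j); }
  int m = eu.size();
  long accepted = 0;
  if (m >= 2) {
    for (int t = 0; t < n_trials; ++t) {
      int e1 = (int)(unif_rand() * m);
      int e2 = (int)(unif_rand() * m);
      if (e1 == e2) continue;
      int aa = eu[e1], bb = ev[e1], cc = eu[e2], dd = ev[e2];
      // randomize orientation of the second edge
      if (unif_rand() < 0.5) { int tmp = cc; cc = dd; dd = tmp; }
      if (aa == cc || aa == dd || bb == cc || bb == dd) continue;
      if (a(aa, dd) != 0 || a(cc, bb) != 0) continue;
      a(aa, bb) = a(bb, aa) = 0;
      a(cc, dd) = a(dd, cc) = 0;
      a(aa, dd) = a(dd, aa) = 1;
      a(cc, bb) = a(bb, cc) = 1;
      eu[e1] = aa; ev[e1] = dd;
      eu[e2] = cc < bb ? cc : bb; ev[e2] = cc < bb ? bb : cc;
      // keep (u,v) ordered for e1 too
      if (eu[e1] > ev[e1]) { int tmp = eu[e1]; eu[e1] = ev[e1]; ev[e1] = tmp; }
      ++accepted;
    }
  }
  return List::create(_["adjacency"] = a, _["n_swaps"] = (double)accepted);
}
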