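#include <Rcpp.h>
using namespace Rcpp;

// Adjacency comes in as a list of 1-based integer vectors, one per node,
// sorted ascending. Node indices follow the graph's lexicographic symbol
// order, so "smallest index" == "lexicographically smallest symbol".

static std::vector<std::vector<int>> to_adj(const List& adj, int n) {
  std::vector<std::vector<int>> A(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector ai = adj[i];
    A[i].reserve(ai.size());
    for (int v : ai) A[i].push_back(v - 1);
  }
  return A;
}

// All-pairs unweighted shortest-path distances; -1 marks unreachable.
// [[Rcpp::export]]
IntegerMatrix cpp_all_pairs_dist(List adj, int n) {
  std::vector<std::vector<int>> A = to_adj(adj, n);
  IntegerMatrix D(n, n);
  std::fill(D.begin(), D.end(), -1);
  std::vector<int> q(n);
  for (int s = 0; s < n; ++s) {
    int head = 0, tail = 0;
    D(s, s) = 0;
    q[tail++] = s;
    while (head < tail) {
      int u = q[head++];
      for (int w : A[u]) {
        if (D(s, w) < 0) {
          D(s, w) = D(s, u) + 1;
          q[tail++] = w;
        }
      }
    }
  }
  return D;
}

// Brandes accumulation over all sources, extended with the stress variant:
// betweenness delta uses sigma ratios, stress delta uses raw geodesic
// counts. Both are halved at the end so pairs are counted unordered.
// [[Rcpp::export]]
List cpp_brandes(List adj, int n) {
  std::vector<std::vector<int>> A = to_adj(adj, n);
  NumericVector bet(n), str(n);
  std::vector<int> dist(n), q(n);
  std::vector<int> order;
  order.reserve(n);
  std::vector<double> sigma(n), delta(n), delta_s(n);
  std::vector<std::vector<int>> pred(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    order.clear();
    int head = 0, tail = 0;
    dist[s] = 0;
    sigma[s] = 1.0;
    q[tail++] = s;
    while (head < tail) {
      int u = q[head++];
      order.push_back(u);
      for (int w : A[u]) {
        if (dist[w] < 0) {
          dist[w] = dist[u] + 1;
          q[tail++] = w;
        }
        if (dist[w] == dist[u] + 1) {
          sigma[w] += sigma[u];
          pred[w].push_back(u);
        }
      }
    }
    std::fill(delta.begin(), delta.end(), 0.0);
    std::fill(delta_s.begin(), delta_s.end(), 0.0);
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int w = order[i];
      for (int u : pred[w]) {
        delta[u] += sigma[u] / sigma[w] * (1.0 + delta[w]);
        delta_s[u] += sigma[u] * (1.0 + delta_s[w] / sigma[w]);
      }
      if (w != s) {
        bet[w] += delta[w];
        str[w] += delta_s[w];
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    bet[i] /= 2.0;
    str[i] /= 2.0;
  }
  return List::create(_["betweenness"] = bet, _["stress"] = str);
}

// Bottleneck: for every root s, build the BFS shortest-path tree whose
// parent choice is the smallest-index predecessor (deterministic), then
// count, for each v != s, the roots whose tree hangs a subtree of more
// than comp_size/4 nodes at v.
// [[Rcpp::export]]
IntegerVector cpp_bottleneck(List adj, int n) {
  std::vector<std::vector<int>> A = to_adj(adj, n);
  IntegerVector res(n);
  std::vector<int> dist(n), q(n), parent(n), cnt(n);

  // component sizes via BFS labelling
  std::vector<int> comp(n, -1);
  std::vector<int> comp_size;
  for (int s = 0; s < n; ++s) {
    if (comp[s] >= 0) continue;
    int c = (int)comp_size.size(), sz = 0;
    int head = 0, tail = 0;
    comp[s] = c;
    q[tail++] = s;
    while (head < tail) {
      int u = q[head++];
      ++sz;
      for (int w : A[u])
        if (comp[w] < 0) { comp[w] = c; q[tail++] = w; }
    }
    comp_size.push_back(sz);
  }

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    dist[s] = 0;
    parent[s] = -1;
    q[tail++] = s;
    while (head < tail) {
      int u = q[head++];
      for (int w : A[u]) {
        if (dist[w] < 0) {
          dist[w] = dist[u] + 1;
          parent[w] = u;  // first discovery comes from the smallest-index
                          // frontier node; refined below
          q[tail++] = w;
        } else if (dist[w] == dist[u] + 1 && u < parent[w]) {
          parent[w] = u;
        }
      }
    }
    // subtree sizes: walk BFS order backwards
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = tail - 1; i >= 0; --i) {
      int w = q[i];
      cnt[w] += 1;
      if (parent[w] >= 0) cnt[parent[w]] += cnt[w];
    }
    int nc = comp_size[comp[s]];
    for (int i = 0; i < tail; ++i) {
      int v = q[i];
      if (v != s && 4 * cnt[v] > nc) res[v] += 1;
    }
  }
  return res;
}

// Edge-percolated component: Monte-Carlo mean size of each node's
// connected component when every edge is kept independently with
// probability retain_p. Uses R's RNG so set.seed() governs the draws.
// edges: m x 2 matrix of 1-based endpoints in a fixed order.
// [[Rcpp::export]]
NumericVector cpp_epc(IntegerMatrix edges, int n, double retain_p, int iterations) {
  int m = edges.nrow();
  NumericVector acc(n);
  std::vector<int> parent(n), size(n);
  RNGScope scope;
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < n; ++i) { parent[i] = i; size[i] = 1; }
    for (int e = 0; e < m; ++e) {
      if (unif_rand() < retain_p) {
        int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
        while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
        while (parent[b] != b) { parent[b] = parent[parent[b]]; b = parent[b]; }
        if (a != b) {
          if (size[a] < size[b]) std::swap(a, b);
          parent[b] = a;
          size[a] += size[b];
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      int r = i;
      while (parent[r] != r) { parent[r] = parent[parent[r]]; r = parent[r]; }
      acc[i] += size[r];
    }
  }
  return acc / (double)iterations;
}
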