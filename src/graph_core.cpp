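#include <Rcpp.h>
#include <vector>
#include <utility>
#include <algorithm>
#include <cmath>
#include <queue>
#include <functional>
using namespace Rcpp;

// ---- all-pairs shortest paths ------------------------------------------

// Exact all-pairs shortest paths on edge lengths 1/weight; unreachable
// pairs are +Inf.  Two exact strategies, picked by density: a
// vectorizable Floyd-Warshall sweep for the dense thresholds, and
// per-source Dijkstra with a binary heap for the sparse ones.
// [[Rcpp::export]]
NumericMatrix apsp_distances_cpp(const NumericMatrix& W) {
  const int n = W.nrow();
  NumericMatrix D(n, n);
  double* d = D.begin();  // column-major; input symmetric
  long m2 = 0;            // directed edge count
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      const bool e = (i != j) && W(i, j) > 0.0;
      d[i + (size_t) n * j] = (i == j) ? 0.0
                            : (e ? 1.0 / W(i, j) : R_PosInf);
      if (e) ++m2;
    }
  const double density = n > 1 ? (double) m2 / ((double) n * (n - 1)) : 0.0;

  if (density > 0.25 || n < 32) {  // Floyd-Warshall
    for (int k = 0; k < n; ++k) {
      const double* dk = d + (size_t) n * k;
      for (int j = 0; j < n; ++j) {
        const double dkj = d[k + (size_t) n * j];
        if (!std::isfinite(dkj)) continue;
        double* dj = d + (size_t) n * j;
        for (int i = 0; i < n; ++i) {
          const double via = dk[i] + dkj;
          if (via < dj[i]) dj[i] = via;
        }
      }
    }
    return D;
  }

  // sparse: Dijkstra from each source, lazy-deletion binary heap
  std::vector<int> head(n + 1, 0), to((size_t) m2);
  std::vector<double> len((size_t) m2);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && W(i, j) > 0.0) ++head[i + 1];
  for (int i = 0; i < n; ++i) head[i + 1] += head[i];
  {
    std::vector<int> pos(head.begin(), head.end() - 1);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (i != j && W(i, j) > 0.0) {
          to[pos[i]] = j;
          len[pos[i]] = 1.0 / W(i, j);
          ++pos[i];
        }
  }
  std::vector<double> dist(n);
  typedef std::pair<double, int> QE;
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    dist[s] = 0.0;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > q;
    q.push(QE(0.0, s));
    while (!q.empty()) {
      const double du = q.top().first;
      const int u = q.top().second;
      q.pop();
      if (du > dist[u]) continue;  // stale entry
      for (int e = head[u]; e < head[u + 1]; ++e) {
        const double nd = du + len[e];
        if (nd < dist[to[e]]) {
          dist[to[e]] = nd;
          q.push(QE(nd, to[e]));
        }
      }
    }
    for (int v = 0; v < n; ++v) d[v + (size_t) n * s] = dist[v];
  }
  return D;
}

// mean shortest-path distance over reachable ordered pairs (NaN if none)
// [[Rcpp::export]]
double char_path_length_cpp(const NumericMatrix& D) {
  const int n = D.nrow();
  double s = 0.0;
  long cnt = 0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (i != j && std::isfinite(D(i, j))) { s += D(i, j); ++cnt; }
  if (cnt == 0) return NA_REAL;
  return s / (double) cnt;
}

// ---- Onnela weighted clustering ----------------------------------------

// C_i = sum_{j<h in N(i)} 2 * (w^_ij w^_ih w^_jh)^{1/3} / (k_i (k_i-1)),
// with weights normalized by the network maximum.  Cube roots are taken
// once per edge.
// [[Rcpp::export]]
NumericVector onnela_clustering_cpp(const NumericMatrix& W) {
  const int n = W.nrow();
  NumericVector C(n);
  double mx = 0.0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (W(i, j) > mx) mx = W(i, j);
  if (mx <= 0.0) return C;
  // cube-root matrix of normalized weights, 0 where no edge
  std::vector<double> A((size_t) n * n, 0.0);
  std::vector< std::vector<int> > nb(n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (i != j && W(i, j) > 0.0) {
        A[i + (size_t) n * j] = std::cbrt(W(i, j) / mx);
        if (i < j) { nb[i].push_back(j); nb[j].push_back(i); }
      }
  for (int i = 0; i < n; ++i) {
    const int k = (int) nb[i].size();
    if (k < 2) { C[i] = 0.0; continue; }
    double s = 0.0;
    for (int a = 0; a < k; ++a) {
      const int j = nb[i][a];
      const double aij = A[i + (size_t) n * j];
      for (int b = a + 1; b < k; ++b) {
        const int h = nb[i][b];
        const double ajh = A[j + (size_t) n * h];
        if (ajh > 0.0) s += aij * A[i + (size_t) n * h] * ajh;
      }
    }
    C[i] = 2.0 * s / ((double) k * (k - 1));
  }
  return C;
}

// ---- degree-preserving rewiring ----------------------------------------

static void rewire_in_place(std::vector<double>& A, int n,
                            std::vector<int>& ea, std::vector<int>& eb,
                            int n_swaps_per_edge) {
  const int m = (int) ea.size();
  if (m < 2) return;
  const long attempts = (long) n_swaps_per_edge * (long) m;
  for (long t = 0; t < attempts; ++t) {
    int e1 = (int) (unif_rand() * m); if (e1 >= m) e1 = m - 1;
    int e2 = (int) (unif_rand() * m); if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
    if (unif_rand() < 0.5) std::swap(c, d);  // covers both orientations
    if (a == c || a == d || b == c || b == d) continue;
    if (A[a + (size_t) n * d] > 0.0 || A[b + (size_t) n * c] > 0.0)
      continue;
    const double w1 = A[a + (size_t) n * b];
    const double w2 = A[c + (size_t) n * d];
    A[a + (size_t) n * b] = A[b + (size_t) n * a] = 0.0;
    A[c + (size_t) n * d] = A[d + (size_t) n * c] = 0.0;
    A[a + (size_t) n * d] = A[d + (size_t) n * a] = w1;
    A[b + (size_t) n * c] = A[c + (size_t) n * b] = w2;
    ea[e1] = std::min(a, d); eb[e1] = std::max(a, d);
    ea[e2] = std::min(b, c); eb[e2] = std::max(b, c);
  }
}

static void edge_list(const NumericMatrix& W, std::vector<int>& ea,
                      std::vector<int>& eb) {
  const int n = W.nrow();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (W(i, j) > 0.0) { ea.push_back(i); eb.push_back(j); }
}

// One degree-preserving randomization of a weighted undirected graph by
// repeated double-edge swaps (a-b, c-d) -> (a-d, b-c).  A swap is
// rejected if it would create a self-loop or a parallel edge, so the
// degree sequence is invariant; each weight travels with its edge, so
// the weight multiset and total weight are invariant too.  Uses R's RNG
// (unif_rand), hence reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix rewire_weighted_cpp(const NumericMatrix& W,
                                  const int n_swaps_per_edge) {
  const int n = W.nrow();
  std::vector<double> A(W.begin(), W.end());
  std::vector<int> ea, eb;
  edge_list(W, ea, eb);
  rewire_in_place(A, n, ea, eb, n_swaps_per_edge);
  NumericMatrix out(n, n);
  std::copy(A.begin(), A.end(), out.begin());
  return out;
}

// Null-ensemble summary used by small-worldness: for each of n_random
// rewired nulls of W, the mean Onnela clustering coefficient and the
// characteristic path length.  Keeping the loop in C++ avoids per-null
// matrix copies through R.
// [[Rcpp::export]]
NumericMatrix null_ensemble_stats_cpp(const NumericMatrix& W,
                                      const int n_random,
                                      const int n_swaps_per_edge) {
  const int n = W.nrow();
  NumericMatrix out(n_random, 2);
  NumericMatrix Wn(n, n);
  for (int r = 0; r < n_random; ++r) {
    std::vector<double> A(W.begin(), W.end());
    std::vector<int> ea, eb;
    edge_list(W, ea, eb);
    rewire_in_place(A, n, ea, eb, n_swaps_per_edge);
    std::copy(A.begin(), A.end(), Wn.begin());
    NumericVector C = onnela_clustering_cpp(Wn);
    out(r, 0) = mean(C);
    out(r, 1) = char_path_length_cpp(apsp_distances_cpp(Wn));
  }
  return out;
}
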