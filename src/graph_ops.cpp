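#include <Rcpp.h>
using namespace Rcpp;

// All-pairs shortest path lengths (Floyd-Warshall) on a dense length matrix.
// len(i, j): edge length > 0, or +Inf where no edge. Diagonal forced to 0.
// Dense FW beats Dijkstra-with-heap here: analysed networks are small
// (tens to a few hundred nodes) and near-complete after density thresholding.
// [[Rcpp::export]]
NumericMatrix fw_distances(NumericMatrix len) {
  int n = len.nrow();
  if (len.ncol() != n) stop("length matrix must be square");
  NumericMatrix d(clone(len));
  double *p = d.begin();  // column-major
  for (int i = 0; i < n; ++i) p[i + (size_t)n * i] = 0.0;
  for (int k = 0; k < n; ++k) {
    const double *colk = p + (size_t)n * k;  // colk[i] = d(i, k)
    for (int j = 0; j < n; ++j) {
      double dkj = p[(size_t)n * j + k];
      if (dkj == R_PosInf) continue;
      double *colj = p + (size_t)n * j;
      for (int i = 0; i < n; ++i) {
        double alt = colk[i] + dkj;
        if (alt < colj[i]) colj[i] = alt;
      }
    }
  }
  return d;
}

// Degree-preserving edge rewiring (Maslov-Sneppen double edge swaps).
// edges: m x 2 matrix of 1-based node indices of an undirected simple graph.
// Attempts swaps until `target_swaps` succeed or `max_attempts` are spent;
// swaps creating self-loops or multi-edges are rejected. Uses R's RNG so
// results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix ms_rewire(IntegerMatrix edges, int n, int target_swaps,
                        int max_attempts) {
  int m = edges.nrow();
  IntegerMatrix e(clone(edges));
  if (m < 2) return e;
  std::vector<bool> adj((size_t)n * (size_t)n, false);
  for (int t = 0; t < m; ++t) {
    int a = e(t, 0) - 1, b = e(t, 1) - 1;
    if (a < 0 || b < 0 || a >= n || b >= n) stop("edge index out of range");
    adj[(size_t)a * n + b] = true;
    adj[(size_t)b * n + a] = true;
  }
  int swaps = 0, attempts = 0;
  while (swaps < target_swaps && attempts < max_attempts) {
    ++attempts;
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int a = e(e1, 0) - 1, b = e(e1, 1) - 1;
    int c = e(e2, 0) - 1, d = e(e2, 1) - 1;
    // randomly flip one edge's orientation so both swap variants are reachable
    if (unif_rand() < 0.5) std::swap(c, d);
    if (a == c || a == d || b == c || b == d) continue;
    if (adj[(size_t)a * n + d] || adj[(size_t)c * n + b]) continue;
    adj[(size_t)a * n + b] = adj[(size_t)b * n + a] = false;
    adj[(size_t)c * n + d] = adj[(size_t)d * n + c] = false;
    adj[(size_t)a * n + d] = adj[(size_t)d * n + a] = true;
    adj[(size_t)c * n + b] = adj[(size_t)b * n + c] = true;
    e(e1, 0) = a + 1; e(e1, 1) = d + 1;
    e(e2, 0) = c + 1; e(e2, 1) = b + 1;
    ++swaps;
  }
  return e;
}
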