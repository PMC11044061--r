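# Brute-force oracles, deliberately naive and independent of the package's
# implementations: triple loops for triangle-based metrics, igraph (Dijkstra /
# component search) for path-based metrics and connectivity.

oracle_tri_num <- function(W, i) {
  n <- nrow(W)
  acc <- 0
  for (j in seq_len(n)) for (h in seq_len(n)) {
    if (j != i && h != i && h != j)
      acc <- acc + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
  }
  acc
}

oracle_transitivity <- function(W) {
  k <- rowSums(W > 0)
  den <- sum(k * (k - 1))
  if (den == 0) return(0)
  num <- sum(vapply(seq_len(nrow(W)), function(i) oracle_tri_num(W, i), 0))
  num / den
}

oracle_clustering <- function(W) {
  k <- rowSums(W > 0)
  vapply(seq_len(nrow(W)), function(i) {
    if (k[i] < 2) return(0)
    oracle_tri_num(W, i) / (k[i] * (k[i] - 1))
  }, 0)
}

oracle_distances <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

oracle_efficiency <- function(W) {
  n <- nrow(W)
  D <- oracle_distances(W)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_cpl <- function(W) {
  D <- oracle_distances(W)
  d <- D[row(D) != col(D)]
  mean(d[is.finite(d)])
}

oracle_connected <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  igraph::components(g)$no == 1
}

# random symmetric weight matrix in [0, 1], zero diagonal, edge prob p
rand_graph <- function(n, p, seed) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  w <- runif(sum(ut))
  w[runif(sum(ut)) > p] <- 0
  W[ut] <- w
  W + t(W)
}
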