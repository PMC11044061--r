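check_weight_matrix <- function(W, check_sym = TRUE) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (anyNA(W) || any(!is.finite(W))) stop("weight matrix contains NA/Inf")
  if (any(W < 0) || any(W > 1)) stop("weights must lie in [0, 1]")
  if (any(diag(W) != 0)) stop("diagonal must be 0")
  if (check_sym && any(abs(W - t(W)) > 1e-12))
    stop("weight matrix must be symmetric")
  invisible(W)
}

#' Weighted shortest path lengths
#'
#' All-pairs shortest path lengths with edge length defined as the inverse
#' weight (the usual convention for similarity-weighted connectomes: stronger
#' edges are shorter). Unreachable pairs get \code{Inf}.
#'
#' @param W Symmetric weight matrix, weights in \[0, 1\], zero diagonal.
#' @return Matrix of path lengths (zero diagonal).
#' @export
shortest_path_lengths <- function(W) {
  check_weight_matrix(W)
  D <- .spl(W)
  dimnames(D) <- dimnames(W)
  D
}

# unchecked kernels used in hot loops (inputs validated once by the caller)
.spl <- function(W) {
  len <- 1 / W
  len[W == 0] <- Inf
  diag(len) <- 0
  fw_distances(len)
}

.tri_deg <- function(W) {
  W3 <- W^(1 / 3)
  list(tri = diag(W3 %*% W3 %*% W3), k = rowSums(W > 0))
}

.transitivity <- function(td) {
  den <- sum(td$k * (td$k - 1))
  if (den == 0) 0 else sum(td$tri) / den
}

.clustering <- function(td) {
  ifelse(td$k >= 2, td$tri / (td$k * (td$k - 1)), 0)
}

.global_eff <- function(D) {
  n <- nrow(D)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted transitivity
#'
#' Whole-network ratio of weighted closed triplets to connected triplets,
#' the network-level analogue of the clustering coefficient that is robust to
#' poorly connected nodes. With \eqn{W^{1/3}} the elementwise cube root of the
#' weight matrix and \eqn{k_i} the binary degree,
#' \deqn{T = \sum_i [(W^{1/3})^3]_{ii} / \sum_i k_i (k_i - 1).}
#' Returns 0 when no node has degree >= 2.
#'
#' @param W Symmetric weight matrix, weights in \[0, 1\], zero diagonal.
#' @return Transitivity in \[0, 1\].
#' @export
#' @examples
#' tri <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3)
#' transitivity_w(tri)  # 1
transitivity_w <- function(W) {
  check_weight_matrix(W)
  .transitivity(.tri_deg(W))
}

#' Weighted clustering coefficient (per node)
#'
#' Geometric-mean weighted triangle intensity around each node:
#' \deqn{c_i = [(W^{1/3})^3]_{ii} / (k_i (k_i - 1)),}
#' with \eqn{k_i} the binary degree; 0 for nodes of degree < 2.
#'
#' @param W Symmetric weight matrix, weights in \[0, 1\], zero diagonal.
#' @return Numeric vector of per-node coefficients in \[0, 1\].
#' @export
clustering_w <- function(W) {
  check_weight_matrix(W)
  out <- .clustering(.tri_deg(W))
  names(out) <- rownames(W)
  out
}

#' Weighted global efficiency
#'
#' Mean inverse shortest path length over all ordered node pairs, a measure
#' of network integration:
#' \deqn{E = \frac{1}{n(n-1)} \sum_{i \ne j} 1 / d_{ij},}
#' with \eqn{d_{ij}} the shortest weighted path length (edge length
#' \eqn{1/w}); unreachable pairs contribute 0. For weights normalised to
#' \[0, 1\] this lies in \[0, 1\].
#'
#' @param W Symmetric weight matrix, weights in \[0, 1\], zero diagonal.
#' @return Global efficiency in \[0, 1\].
#' @export
#' @examples
#' path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
#' global_efficiency_w(path3)  # 5/6
global_efficiency_w <- function(W) {
  check_weight_matrix(W)
  if (nrow(W) < 2) return(0)
  .global_eff(.spl(W))
}

#' Characteristic path length
#'
#' Mean shortest weighted path length over reachable ordered node pairs. A
#' disconnected network triggers a warning and the mean is taken over the
#' reachable pairs only (infinities would otherwise make the metric useless
#' at low densities).
#'
#' @param W Symmetric weight matrix, weights in \[0, 1\], zero diagonal.
#' @param warn Warn when unreachable pairs are dropped (default \code{TRUE}).
#' @return Mean path length (> 0).
#' @export
char_path_length <- function(W, warn = TRUE) {
  n <- nrow(W)
  if (n < 2) stop("characteristic path length undefined for a single node")
  D <- shortest_path_lengths(W)
  d <- D[row(D) != col(D)]
  reach <- is.finite(d)
  if (!all(reach)) {
    if (warn) warning("network is disconnected; path length computed over reachable pairs")
    d <- d[reach]
    if (length(d) == 0) stop("no reachable pairs: network has no edges")
  }
  mean(d)
}

#' Is the network connected?
#'
#' \code{TRUE} iff a single component (over non-zero weights) spans all nodes.
#'
#' @param W Symmetric weight matrix.
#' @return Logical scalar.
#' @export
is_connected_graph <- function(W) {
  n <- nrow(W)
  if (n <= 1) return(TRUE)
  A <- W > 0
  reach <- logical(n)
  reach[1] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !reach)
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  all(reach)
}

# Upper-triangle edge list (i, j, w) of a weight matrix.
edge_list <- function(W) {
  ut <- which(upper.tri(W) & W > 0)
  ij <- arrayInd(ut, dim(W))
  cbind(i = ij[, 1], j = ij[, 2], w = W[ut])
}

#' Small-worldness coefficient
#'
#' \deqn{\sigma = (C / C_{rand}) / (L / L_{rand})}
#' with C the mean weighted clustering coefficient ([clustering_w()]), L the
#' characteristic path length ([char_path_length()]), and the rand terms
#' averaged over \code{n_null} degree-preserving rewired null networks
#' (Maslov-Sneppen double edge swaps) that retain the empirical weight
#' multiset, reassigned to the rewired edges at random. Values above 1
#' indicate small-world organisation (clustered yet well integrated).
#'
#' @param W Symmetric weight matrix, weights in \[0, 1\], zero diagonal;
#'   must be connected.
#' @param n_null Number of null networks (default 10).
#' @param seed Optional integer seed making the null ensemble reproducible;
#'   per-null sub-seeds are derived from it.
#' @return Small-worldness sigma (> 0).
#' @export
small_worldness <- function(W, n_null = 10L, seed = NULL) {
  check_weight_matrix(W)
  if (n_null < 1) stop("n_null must be >= 1")
  if (!is_connected_graph(W))
    stop("small-worldness requires a connected network")
  C_obs <- mean(clustering_w(W))
  L_obs <- char_path_length(W)
  ed <- edge_list(W)
  m <- nrow(ed)
  if (m < 2) stop("too few edges for rewiring")
  n <- nrow(W)
  C_null <- L_null <- numeric(n_null)
  for (b in seq_len(n_null)) {
    if (!is.null(seed)) set.seed(derive_seed(seed, b))
    re <- ms_rewire(ed[, 1:2, drop = FALSE], n, 10L * m, 200L * m)
    wnull <- sample(ed[, 3])
    Wn <- array(0, dim = c(n, n))
    Wn[re] <- wnull
    Wn[re[, 2:1, drop = FALSE]] <- wnull
    C_null[b] <- mean(clustering_w(Wn))
    L_null[b] <- char_path_length(Wn, warn = FALSE)
  }
  (C_obs / mean(C_null)) / (L_obs / mean(L_null))
}

#' Compute subnetwork graph metrics across density thresholds
#'
#' For each subject's similarity matrix, extracts each analysis subnetwork,
#' thresholds it at each density (see [threshold_density()]; thresholding is
#' applied to the induced subnetwork so the density is exact within each
#' analysed network), and computes transitivity, global efficiency, a
#' connectivity flag and (optionally) small-worldness.
#'
#' @param msns Named list of per-subject similarity matrices
#'   ([build_msn()] output), or an \code{msn_morphometry} object (matrices are
#'   built on the fly).
#' @param atlas Atlas data.frame.
#' @param networks Named list of [network_definition()] objects
#'   (default [builtin_networks()]).
#' @param densities Density thresholds (default 0.25 to 0.45 in steps of 0.05).
#' @param small_world Also compute the small-world coefficient
#'   (default \code{FALSE}; it costs \code{n_null} null-network realisations
#'   per subject, network and density).
#' @param n_null Null networks per small-worldness evaluation.
#' @param seed Seed for the small-worldness null ensembles.
#' @param metrics Which of \code{"transitivity"} and
#'   \code{"global_efficiency"} to compute; a metric left out is reported as
#'   \code{NA} (saves its computation in large simulation studies).
#' @return Long-format data.frame: \code{subject_id}, \code{network},
#'   \code{density}, \code{transitivity}, \code{global_efficiency},
#'   \code{small_worldness} (NA unless requested), \code{connected}.
#' @export
compute_metrics <- function(msns, atlas, networks = builtin_networks(),
                            densities = seq(0.25, 0.45, by = 0.05),
                            small_world = FALSE, n_null = 10L,
                            seed = NULL,
                            metrics = c("transitivity", "global_efficiency")) {
  if (any(diff(densities) <= 0) || any(densities <= 0) || any(densities > 1))
    stop("densities must be strictly increasing values in (0, 1]")
  metrics <- match.arg(metrics, several.ok = TRUE)
  node_sets <- lapply(networks, function(def) network_nodes(atlas, def))
  if (inherits(msns, "msn_morphometry")) {
    # build only the rows the analysed subnetworks need: features are
    # z-scored across all regions first, so the induced similarities are
    # identical to extracting them from the full matrix
    keep <- sort(unique(unlist(node_sets)))
    msns <- lapply(msns, function(X)
      .cor_clamp(standardize_features(X)[keep, , drop = FALSE]))
    node_sets <- lapply(node_sets, function(idx) match(idx, keep))
  }
  if (is.null(names(msns)) || any(!nzchar(names(msns))))
    stop("'msns' must be a named list of similarity matrices")
  n_rows <- length(msns) * length(networks) * length(densities)
  col_sid <- col_net <- character(n_rows)
  col_d <- col_t <- col_e <- col_sw <- numeric(n_rows)
  col_conn <- logical(n_rows)
  want_t <- "transitivity" %in% metrics
  want_e <- "global_efficiency" %in% metrics
  r <- 0L
  for (s in seq_along(msns)) {
    check_weight_matrix(msns[[s]], check_sym = FALSE)
    for (nw in names(networks)) {
      sub <- extract_subnetwork(msns[[s]], node_sets[[nw]])
      for (d in densities) {
        Wt <- threshold_density(sub, d)
        conn <- is_connected_graph(Wt)
        sw <- NA_real_
        if (small_world && conn) {
          sw_seed <- if (is.null(seed)) NULL else
            derive_seed(seed, s * 131071L + match(nw, names(networks)) * 8191L +
                          round(d * 100))
          sw <- small_worldness(Wt, n_null = n_null, seed = sw_seed)
        }
        r <- r + 1L
        col_sid[r] <- names(msns)[s]
        col_net[r] <- nw
        col_d[r] <- d
        col_t[r] <- if (want_t) .transitivity(.tri_deg(Wt)) else NA_real_
        col_e[r] <- if (want_e) .global_eff(.spl(Wt)) else NA_real_
        col_sw[r] <- sw
        col_conn[r] <- conn
      }
    }
  }
  data.frame(subject_id = col_sid, network = col_net, density = col_d,
             transitivity = col_t, global_efficiency = col_e,
             small_worldness = col_sw, connected = col_conn,
             stringsAsFactors = FALSE)
}
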