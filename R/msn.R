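# Coerce a morphometric input (matrix, or data.frame with a region_id column)
# to a numeric regions x features matrix with region_id rownames.
as_morph_matrix <- function(table) {
  if (is.data.frame(table)) {
    ids <- NULL
    if ("region_id" %in% names(table)) {
      ids <- table$region_id
      table <- table[setdiff(names(table), c("region_id", "subject_id"))]
    }
    table <- as.matrix(table)
    if (!is.null(ids)) rownames(table) <- ids
  }
  if (!is.numeric(table)) stop("morphometric table must be numeric")
  if (anyNA(table) || any(!is.finite(table)))
    stop("morphometric table contains missing or non-finite values")
  table
}

#' Z-score morphometric features across regions
#'
#' Standardises each feature column to mean 0 and sample SD 1 across the
#' subject's regions. Raw FreeSurfer features live on incommensurate scales
#' (mm^3, mm^2, mm, dimensionless curvature indices), so inter-regional
#' correlations of raw feature vectors would be dominated by the large-valued
#' features; z-scoring puts all features on an equal footing before
#' correlation.
#'
#' @param table Regions x features numeric matrix (or data.frame with a
#'   \code{region_id} column).
#' @return Matrix of the same shape, each column with mean 0 and sample SD 1.
#' @export
standardize_features <- function(table) {
  X <- as_morph_matrix(table)
  sds <- apply(X, 2, sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero) > 0) {
    nm <- colnames(X)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop("degenerate input: zero-variance feature column(s): ",
         paste(nm, collapse = ", "))
  }
  scale(X)[, , drop = FALSE]
}

#' Build a morphometric similarity matrix
#'
#' Computes the pairwise Pearson correlation between every two regions'
#' feature vectors, then removes self-correlations (diagonal set to 0) and
#' negative correlations (clamped to 0), yielding a symmetric similarity
#' matrix with weights in \[0, 1\]. Features are z-scored across regions
#' first (see [standardize_features()]) unless \code{standardize = FALSE}.
#'
#' A region whose standardized feature vector has zero variance has no
#' defined correlation with any other region; its similarities are set to 0
#' with a warning rather than failing, so large synthetic runs survive
#' pathological draws.
#'
#' @param table Regions x features matrix (>= 3 regions).
#' @param standardize Z-score feature columns first (default \code{TRUE}).
#' @return Symmetric numeric similarity matrix with zero diagonal, entries in
#'   \[0, 1\], region identifiers as dimnames.
#' @export
#' @examples
#' X <- matrix(rnorm(6 * 7), 6, 7)
#' W <- build_msn(X)
#' range(W)  # within [0, 1]
build_msn <- function(table, standardize = TRUE) {
  X <- as_morph_matrix(table)
  if (nrow(X) < 3) stop("need at least 3 regions to build an MSN")
  if (standardize) X <- standardize_features(X)
  .cor_clamp(X)
}

# pairwise region correlation with negative/self removal; rows of X are
# (already standardized) region feature vectors
.cor_clamp <- function(X) {
  suppressWarnings(W <- cor(t(X)))
  if (anyNA(W)) {
    bad <- rownames(X)[apply(X, 1, sd) == 0]
    warning("region feature vector(s) with zero variance; similarities set to 0",
            if (length(bad) > 0) paste0(": ", paste(bad, collapse = ", ")))
    W[is.na(W)] <- 0
  }
  W[W < 0] <- 0
  diag(W) <- 0
  # guard against floating-point asymmetry from cor()
  W <- (W + t(W)) / 2
  W
}

#' Extract an induced subnetwork
#'
#' Returns the submatrix of a similarity matrix induced by a set of node
#' indices, preserving weights and the given node order.
#'
#' @param matrix Symmetric similarity matrix.
#' @param nodes Integer node indices (unique, within range), e.g. from
#'   [network_nodes()].
#' @return The induced square submatrix.
#' @export
extract_subnetwork <- function(matrix, nodes) {
  n <- nrow(matrix)
  nodes <- as.integer(nodes)
  if (length(nodes) == 0) stop("empty node set")
  if (anyDuplicated(nodes)) stop("duplicate node indices")
  if (any(nodes < 1L | nodes > n)) stop("node index out of range 1..", n)
  matrix[nodes, nodes, drop = FALSE]
}

#' Threshold a weighted network at a fixed edge density
#'
#' Keeps exactly \code{round(density * n * (n - 1) / 2)} largest-weight edges
#' (round half up) of the undirected network and sets all other weights to 0,
#' then normalises the retained weights by their maximum so the strongest
#' retained edge has weight exactly 1. Ties between equal weights are broken
#' by ascending (row, column) index order so that results are bit-reproducible
#' and edge sets nest across increasing densities.
#'
#' If the matrix has fewer positive edges than the density asks for, all
#' positive edges are kept with a warning; a density yielding zero edges is an
#' error.
#'
#' @param matrix Symmetric similarity matrix with zero diagonal and
#'   non-negative weights.
#' @param density Target edge density in (0, 1].
#' @param normalize \code{"max"} (default) divides retained weights by the
#'   retained maximum; \code{"mean"} divides by the retained mean;
#'   \code{"none"} leaves weights untouched.
#' @return The thresholded (and normalised) weight matrix, with attributes
#'   \code{density} and \code{retained_edges}.
#' @export
#' @examples
#' W <- build_msn(matrix(rnorm(10 * 7), 10, 7))
#' Wt <- threshold_density(W, 0.4)
#' attr(Wt, "retained_edges")
threshold_density <- function(matrix, density, normalize = c("max", "mean", "none")) {
  normalize <- match.arg(normalize)
  n <- nrow(matrix)
  if (!is.numeric(density) || length(density) != 1 || density <= 0 || density > 1)
    stop("density must be a single value in (0, 1]")
  if (n != ncol(matrix)) stop("matrix must be square")
  if (any(matrix < 0)) stop("matrix must be non-negative")
  m_possible <- n * (n - 1) / 2
  m <- floor(density * m_possible + 0.5)  # round half up
  if (m < 1) stop("empty network: density ", density, " retains no edges at n = ", n)
  ut <- which(upper.tri(matrix))
  w <- matrix[ut]
  ij <- arrayInd(ut, dim(matrix))
  pos <- w > 0
  n_pos <- sum(pos)
  if (n_pos == 0) stop("empty network: no positive weights to retain")
  if (n_pos < m) {
    warning("only ", n_pos, " positive edges available for target of ", m,
            "; keeping all positive edges")
    m <- n_pos
  }
  ord <- order(-w, ij[, 1], ij[, 2])
  keep <- ord[seq_len(m)]
  out <- array(0, dim = dim(matrix), dimnames = dimnames(matrix))
  kept_w <- w[keep]
  norm <- switch(normalize, max = max(kept_w), mean = mean(kept_w), none = 1)
  kept_w <- kept_w / norm
  out[cbind(ij[keep, 1], ij[keep, 2])] <- kept_w
  out[cbind(ij[keep, 2], ij[keep, 1])] <- kept_w
  attr(out, "density") <- density
  attr(out, "retained_edges") <- m
  out
}
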