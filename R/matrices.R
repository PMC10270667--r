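#' Validate a weighted connection matrix
#'
#' Checks that a matrix is a legal weighted connectivity (correlation)
#' matrix: square, symmetric within tolerance, unit diagonal, with all
#' entries in \[-1, 1\]. Small asymmetries (at or below `tol`) are repaired
#' by averaging the matrix with its transpose; anything larger is an error.
#'
#' @param x Square numeric matrix of edge weights (correlations).
#' @param tol Numerical tolerance for symmetry, the unit diagonal and the
#'   \[-1, 1\] range. Default `1e-8`.
#' @return The validated (and, if needed, symmetrized) matrix.
#' @examples
#' C <- diag(3); C[1, 2] <- C[2, 1] <- 0.5
#' validate_connection_matrix(C)
#' @export
validate_connection_matrix <- function(x, tol = 1e-8) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix.")
  }
  if (nrow(x) != ncol(x)) {
    abort(sprintf("matrix is not square (%d x %d)", nrow(x), ncol(x)))
  }
  if (nrow(x) < 2) abort("connection matrix needs at least 2 nodes")
  if (anyNA(x)) abort("matrix contains missing values")
  asym <- max(abs(x - t(x)))
  if (asym > tol) {
    abort(sprintf("matrix asymmetry %.3g exceeds tolerance %.3g", asym, tol))
  }
  x <- (x + t(x)) / 2
  if (max(abs(diag(x) - 1)) > tol) {
    abort("diagonal entries must equal 1")
  }
  diag(x) <- 1
  rng <- range(x)
  if (rng[1] < -1 - tol || rng[2] > 1 + tol) {
    abort(sprintf("entry out of range [-1, 1]: %.4f", rng[which.max(abs(rng))]))
  }
  x[x > 1] <- 1
  x[x < -1] <- -1
  x
}

# Row-major upper-triangle edge index for deterministic tie-breaking.
# Edge (i, j), i < j, gets index (i-1)*(2n-i)/2 + (j-i): (1,2), (1,3),
# ..., (1,n), (2,3), ...
edge_index_rowmajor <- function(n) {
  ij <- which(upper.tri(diag(n)), arr.ind = TRUE) # column-major order
  i <- ij[, 1]
  j <- ij[, 2]
  (i - 1) * (2 * n - i) / 2 + (j - i)
}

#' Extract the off-diagonal upper triangle of a matrix
#'
#' Returns the strictly-upper-triangular entries in R's native
#' (column-major) order. All metrics in the package operate on this
#' vector; the diagonal is always excluded.
#'
#' @param x Square matrix.
#' @return Numeric vector of length `n*(n-1)/2`.
#' @export
upper_edges <- function(x) {
  x[upper.tri(x)]
}

#' Threshold a connection matrix to its top-fraction key edges
#'
#' Produces the binary key-edge graph used by the Jaccard distance: the
#' `fraction` highest-weighted edges (by signed value) are marked 1, all
#' others 0. Exactly `k = round(fraction * n_edges)` edges are retained.
#' Ties are broken deterministically by ascending row-major edge index so
#' results are bit-reproducible. No positivity filter is applied: if fewer
#' than `k` edges are positive, the largest non-positive edges complete the
#' key set (keeping the key-set size fixed) and a warning is raised.
#'
#' @param x Square symmetric numeric matrix (or a numeric vector, e.g. a
#'   nodal degree vector, in which case entries themselves are thresholded).
#' @param fraction Fraction of edges to keep, in (0, 1].
#' @return For matrix input, a 0/1 symmetric matrix with zero diagonal and
#'   attribute `threshold_rule`; for vector input, a 0/1 vector.
#' @examples
#' C <- diag(4)
#' C[upper.tri(C)] <- c(0.9, 0.5, 0.1, -0.2, 0.7, 0.3)
#' C <- C + t(C) - diag(4) + diag(4) * 0 # symmetrize
#' diag(C) <- 1
#' threshold_top_fraction(C, 1 / 3)
#' @export
threshold_top_fraction <- function(x, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    abort("`fraction` must be a single value in (0, 1]")
  }
  vec_input <- !is.matrix(x)
  if (vec_input) {
    v <- as.numeric(x)
    tie_order <- seq_along(v)
  } else {
    v <- upper_edges(x)
    tie_order <- edge_index_rowmajor(nrow(x))
  }
  k <- round(fraction * length(v))
  if (k == 0) abort("empty key set: fraction too small for this matrix")
  sel <- order(-v, tie_order)[seq_len(k)]
  if (min(v[sel]) <= 0) {
    warn("key set includes non-positive edge weights (fewer than k positive edges)")
  }
  ind <- rep(0, length(v))
  ind[sel] <- 1
  if (vec_input) {
    return(structure(ind, threshold_rule = list(type = "top_fraction",
                                                fraction = fraction, k = k)))
  }
  B <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  B[upper.tri(B)] <- ind
  B <- B + t(B)
  structure(B, threshold_rule = list(type = "top_fraction",
                                     fraction = fraction, k = k))
}

#' Nodal degree vector of a weighted network
#'
#' Weighted degree of each node: the row sums of the connection matrix
#' excluding the diagonal. Every metric except the log-Euclidean
#' Riemannian metric accepts such vectors in place of full matrices.
#'
#' @param x Square symmetric numeric matrix.
#' @return Numeric vector of length `nrow(x)`.
#' @export
degree_vector <- function(x) {
  if (!is.matrix(x)) abort("`x` must be a matrix")
  rowSums(x) - diag(x)
}
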