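# ---- pairwise network distance metrics --------------------------------------
#
# All metrics operate on the off-diagonal upper triangle of the two
# matrices (or directly on a pair of vectors, e.g. nodal degree vectors).
# The diagonal never enters any metric.

metric_values <- function(x) {
  if (is.matrix(x)) upper_edges(x) else as.numeric(x)
}

check_same_length <- function(v1, v2) {
  if (length(v1) != length(v2)) {
    abort(sprintf("dimension mismatch: %d vs %d edge values",
                  length(v1), length(v2)))
  }
}

# Exact two-sample Kolmogorov-Smirnov statistic: sup over all pooled data
# points of |F1 - F2|, tie-aware.
ks_statistic <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  w <- c(rep(1 / na, na), rep(-1 / nb, nb))
  o <- order(pooled)
  cs <- cumsum(w[o])
  ps <- pooled[o]
  last <- c(diff(ps) != 0, TRUE) # evaluate at the last occurrence of ties
  max(abs(cs[last]))
}

#' Kolmogorov-Smirnov distance between edge-weight distributions
#'
#' Natural log of the two-sample Kolmogorov-Smirnov statistic between the
#' empirical distributions of the two networks' edge weights (upper
#' triangle). Values are at most 0 (log of a statistic in (0, 1\]); larger
#' (closer to 0) means more dissimilar. If the two edge-weight multisets
#' are identical the statistic is 0 and its log undefined; the value is
#' then floored at `log(1/n_edges)` — the smallest nonzero statistic
#' attainable at that sample size — and flagged via the `degenerate`
#' attribute.
#'
#' @param x1,x2 Square symmetric matrices (or numeric vectors such as
#'   nodal degree vectors) of equal dimension.
#' @return Log KS statistic (scalar). Attribute `degenerate` is `TRUE`
#'   when the floor was applied.
#' @export
ks_distance <- function(x1, x2) {
  v1 <- metric_values(x1)
  v2 <- metric_values(x2)
  check_same_length(v1, v2)
  d <- ks_statistic(v1, v2)
  if (d <= 0) {
    return(structure(log(1 / length(v1)), degenerate = TRUE))
  }
  log(d)
}

#' Jaccard distance between key-edge sets
#'
#' Proportion of key edges (edges that are key in either graph) that do
#' not share key status: `(M01 + M10) / (M11 + M01 + M10)` over the upper
#' triangle. 0 means perfect overlap, 1 no overlap.
#'
#' @param b1,b2 Binary key-edge graphs from [threshold_top_fraction()]
#'   (0/1 matrices, or 0/1 vectors for the degree-vector variant). Both
#'   must come from the same thresholding rule.
#' @return Jaccard distance in \[0, 1\].
#' @export
jaccard_distance <- function(b1, b2) {
  r1 <- attr(b1, "threshold_rule")
  r2 <- attr(b2, "threshold_rule")
  if (!is.null(r1) && !is.null(r2) && !identical(r1, r2)) {
    abort("binary graphs were produced by different threshold rules")
  }
  v1 <- metric_values(b1)
  v2 <- metric_values(b2)
  check_same_length(v1, v2)
  if (!all(v1 %in% c(0, 1)) || !all(v2 %in% c(0, 1))) {
    abort("inputs must be binary (0/1) key-edge graphs")
  }
  m11 <- sum(v1 == 1 & v2 == 1)
  m01 <- sum(v1 == 0 & v2 == 1)
  m10 <- sum(v1 == 1 & v2 == 0)
  if (m11 + m01 + m10 == 0) {
    abort("both key-edge sets are empty; Jaccard distance undefined")
  }
  (m01 + m10) / (m11 + m01 + m10)
}

#' Euclidean distance between networks
#'
#' Square root of the sum of squared differences over the off-diagonal
#' upper-triangle edge weights (or over vector entries for degree
#' vectors).
#'
#' @inheritParams ks_distance
#' @return Nonnegative scalar.
#' @export
euclidean_distance <- function(x1, x2) {
  v1 <- metric_values(x1)
  v2 <- metric_values(x2)
  check_same_length(v1, v2)
  sqrt(sum((v1 - v2)^2))
}

#' Pearson correlation distance between networks
#'
#' `(1 - r) / 2` where `r` is the Pearson correlation between the two
#' vectorized upper triangles, mapping perfect positive edge-weight
#' correlation to 0 and perfect negative correlation to 1.
#'
#' @inheritParams ks_distance
#' @return Distance in \[0, 1\].
#' @export
pearson_correlation_distance <- function(x1, x2) {
  v1 <- metric_values(x1)
  v2 <- metric_values(x2)
  check_same_length(v1, v2)
  if (sd(v1) == 0 || sd(v2) == 0) {
    abort("constant edge weights: correlation undefined")
  }
  (1 - cor(v1, v2)) / 2
}

# Matrix logarithm of a symmetric positive-definite matrix via
# eigendecomposition; eigenvalues at or below `tol` mean the matrix is not
# usable on the SPD manifold.
spd_logm <- function(x, tol = 1e-10, label = "matrix") {
  e <- eigen(x, symmetric = TRUE)
  if (min(e$values) <= tol) {
    abort(sprintf("%s is not positive-definite (min eigenvalue %.3g)",
                  label, min(e$values)))
  }
  e$vectors %*% (log(e$values) * t(e$vectors))
}

#' Log-Euclidean Riemannian metric (LERM) between SPD networks
#'
#' Frobenius norm of the difference between the matrix logarithms of two
#' symmetric positive-definite connection matrices. Matrix logs are
#' computed by symmetric eigendecomposition; any eigenvalue at or below
#' `tol` raises an error naming the offending input.
#'
#' @param x1,x2 Symmetric positive-definite matrices of equal dimension.
#' @param tol Positivity tolerance for eigenvalues. Default `1e-10`.
#' @return Nonnegative scalar.
#' @export
lerm_distance <- function(x1, x2, tol = 1e-10) {
  if (!is.matrix(x1) || !is.matrix(x2)) {
    abort("LERM requires full SPD matrices (vectors are not supported)")
  }
  if (nrow(x1) != nrow(x2)) abort("dimension mismatch")
  l1 <- spd_logm(x1, tol, "first matrix")
  l2 <- spd_logm(x2, tol, "second matrix")
  norm(l1 - l2, type = "F")
}

# ---- tidy all-pairs distance tables -----------------------------------------

metric_choices <- c("euclidean", "pcd", "ks", "jaccard", "lerm")

scan_table <- function(scans) {
  if (inherits(scans, "bantor_sim")) scans <- scans$scans
  scans <- as_tibble(scans)
  needed <- c("subject", "task", "rep", "matrix")
  if (!all(needed %in% names(scans))) {
    abort("`scans` must have columns subject, task, rep, matrix")
  }
  if (anyDuplicated(scans[c("subject", "task", "rep")])) {
    abort("duplicate (subject, task, rep) scan keys")
  }
  scans
}

#' Pairwise network distances for every same-task scan pair
#'
#' Computes one distance metric for all pairs of scans that share a task,
#' returning a tidy long table ready for [build_design()] (distinct
#' subjects only, the regression path) or [build_distance_matrix()]
#' (`include_within = TRUE`, the MDMR path).
#'
#' @param scans A scan table: tibble with columns `subject`, `task`,
#'   `rep` and a `matrix` list-column of validated connection matrices
#'   (e.g. `simulate_dataset()$scans`).
#' @param metric One of `"euclidean"`, `"pcd"`, `"ks"`, `"jaccard"`,
#'   `"lerm"`.
#' @param threshold Top fraction of edges kept for the Jaccard key-edge
#'   graphs (ignored by other metrics). Default `0.2`.
#' @param include_within Keep same-subject scan pairs? Default `FALSE`
#'   (the regression design uses distinct-subject pairs only).
#' @param degree Compare nodal degree vectors instead of full matrices
#'   (not available for `"lerm"`). Default `FALSE`.
#' @return Tibble with columns `subject1`, `task`, `rep1`, `subject2`,
#'   `rep2`, `metric`, `value`, `degenerate`; attribute `metric` records
#'   the metric (and threshold for Jaccard).
#' @export
network_distances <- function(scans, metric = c("euclidean", "pcd", "ks",
                                                "jaccard", "lerm"),
                              threshold = 0.2, include_within = FALSE,
                              degree = FALSE) {
  metric <- match.arg(metric)
  scans <- scan_table(scans)
  if (degree && metric == "lerm") {
    abort("LERM is defined on SPD matrices, not degree vectors")
  }

  out <- lapply(split(scans, scans$task), function(tk) {
    n <- nrow(tk)
    if (n < 2) return(NULL)
    feats <- scan_features(tk$matrix, metric, threshold, degree)
    pw <- pairwise_values(feats, metric)
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    res <- tibble(
      subject1 = tk$subject[ij[, 1]],
      task = tk$task[ij[, 1]],
      rep1 = tk$rep[ij[, 1]],
      subject2 = tk$subject[ij[, 2]],
      rep2 = tk$rep[ij[, 2]],
      metric = metric,
      value = pw$value,
      degenerate = pw$degenerate
    )
    if (!include_within) res <- res[res$subject1 != res$subject2, ]
    res
  })
  res <- bind_rows(out)
  attr(res, "metric") <- list(metric = metric,
                              threshold = if (metric == "jaccard") threshold)
  res
}

# Per-scan feature rows used by the vectorized pairwise computations:
# upper-triangle values (euclidean/pcd/ks), 0/1 key-edge indicators
# (jaccard), or the vectorized full matrix log (lerm).
scan_features <- function(mats, metric, threshold, degree) {
  if (degree) mats <- lapply(mats, degree_vector)
  if (metric == "lerm") {
    logs <- lapply(seq_along(mats), function(i) {
      as.numeric(spd_logm(mats[[i]], label = sprintf("scan %d", i)))
    })
    return(do.call(rbind, logs))
  }
  vals <- do.call(rbind, lapply(mats, metric_values))
  if (metric == "jaccard") {
    tie_order <- if (is.matrix(mats[[1]])) {
      edge_index_rowmajor(nrow(mats[[1]]))
    } else {
      seq_len(ncol(vals))
    }
    k <- round(threshold * ncol(vals))
    if (k == 0) abort("empty key set: threshold fraction too small")
    keys <- matrix(0, nrow(vals), ncol(vals))
    for (i in seq_len(nrow(vals))) {
      keys[i, order(-vals[i, ], tie_order)[seq_len(k)]] <- 1
    }
    return(keys)
  }
  vals
}

pairwise_values <- function(feats, metric) {
  n <- nrow(feats)
  n_pairs <- n * (n - 1) / 2
  degenerate <- rep(FALSE, n_pairs)
  if (metric %in% c("euclidean", "lerm")) {
    value <- dist_to_uppertri(as.numeric(stats::dist(feats)), n)
  } else if (metric == "pcd") {
    sds <- apply(feats, 1, sd)
    if (any(sds == 0)) abort("constant edge weights: correlation undefined")
    cm <- cor(t(feats))
    value <- (1 - cm[upper.tri(cm)]) / 2
  } else if (metric == "jaccard") {
    m11 <- tcrossprod(feats)
    ksz <- rowSums(feats)
    un <- outer(ksz, ksz, "+") - m11
    if (any(un[upper.tri(un)] == 0)) {
      abort("both key-edge sets empty for some pair")
    }
    jd <- (un - m11) / un
    value <- jd[upper.tri(jd)]
  } else { # ks
    value <- numeric(n_pairs)
    idx <- 0
    ne <- ncol(feats)
    for (j in 2:n) {
      for (i in 1:(j - 1)) {
        idx <- idx + 1
        d <- ks_statistic(feats[i, ], feats[j, ])
        if (d <= 0) {
          value[idx] <- log(1 / ne)
          degenerate[idx] <- TRUE
        } else {
          value[idx] <- log(d)
        }
      }
    }
  }
  list(value = value, degenerate = degenerate)
}

# stats::dist returns pairs in lower-triangle column-major order:
# (2,1),(3,1),...,(n,1),(3,2),... ; reorder to upper-triangle
# column-major order (1,2),(1,3),(2,3),... used throughout.
dist_to_uppertri <- function(d, n) {
  M <- matrix(0, n, n)
  M[lower.tri(M)] <- d
  M <- M + t(M)
  M[upper.tri(M)]
}
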