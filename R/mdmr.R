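# ---- permutation multivariate distance matrix regression (MDMR) ------------

#' Permutation MDMR on a scan distance matrix
#'
#' Multivariate distance matrix regression baseline: the distance matrix
#' is Gower-centered, `G = -1/2 * H (D o D) H` with `H = I - 11'/n`, and
#' each predictor is tested with a pseudo-F statistic comparing its
#' marginal hat-matrix trace contribution to the residual trace.
#' Significance is assessed by jointly permuting the rows and columns of
#' `G`; the p-value uses the add-one estimator
#' `(1 + #permuted F >= observed) / (1 + n_perm)` so it is never exactly
#' zero. MDMR does not account for within-subject correlation; it is
#' included for comparison.
#'
#' @param D Symmetric distance matrix with zero diagonal (e.g.
#'   `build_distance_matrix()$D`).
#' @param predictors Data frame of scan-level predictors (one row per
#'   row of `D`), or a numeric design matrix. An intercept is added.
#' @param n_perm Number of permutations (default 5000).
#' @param seed Optional RNG seed for the permutations.
#' @return A tibble with one row per predictor term: `term`,
#'   `statistic` (pseudo-F), `p.value`, `n_perm`.
#' @export
mdmr_permutation <- function(D, predictors, n_perm = 5000, seed = NULL) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("`D` must be square")
  if (max(abs(D - t(D))) > 1e-8) abort("`D` must be symmetric")
  if (n_perm < 1) abort("`n_perm` must be at least 1")
  n <- nrow(D)

  if (is.matrix(predictors)) {
    X <- cbind(`(Intercept)` = 1, predictors)
    assign_id <- c(0, seq_len(ncol(predictors)))
    term_labels <- colnames(predictors)
  } else {
    predictors <- as.data.frame(predictors)
    mm <- model.matrix(~., data = predictors)
    X <- mm
    assign_id <- attr(mm, "assign")
    term_labels <- attr(stats::terms(~., data = predictors), "term.labels")
  }
  if (qr(X)$rank < ncol(X)) abort("predictor design is rank deficient")

  Hfull <- X %*% solve(crossprod(X), t(X))
  ctr <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * ctr %*% (D * D) %*% ctr

  p <- ncol(X)
  terms_idx <- sort(unique(assign_id[assign_id > 0]))
  Hj <- lapply(terms_idx, function(j) {
    keep <- assign_id != j
    Xr <- X[, keep, drop = FALSE]
    Hfull - Xr %*% solve(crossprod(Xr), t(Xr))
  })
  mj <- vapply(terms_idx, function(j) sum(assign_id == j), numeric(1))
  R <- diag(n) - Hfull

  pseudo_f <- function(Gm) {
    den <- sum(R * Gm) / (n - p)
    vapply(seq_along(Hj), function(k) {
      (sum(Hj[[k]] * Gm) / mj[k]) / den
    }, numeric(1))
  }

  f_obs <- pseudo_f(G)
  if (!is.null(seed)) set.seed(seed)
  exceed <- rep(0, length(f_obs))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    exceed <- exceed + (pseudo_f(G[idx, idx]) >= f_obs)
  }
  tibble(term = term_labels,
         statistic = f_obs,
         p.value = (1 + exceed) / (1 + n_perm),
         n_perm = n_perm)
}
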