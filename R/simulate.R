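# ---- SPD connectome simulator ----------------------------------------------
#
# Simulates whole datasets of symmetric positive-definite correlation
# matrices ("scans") with known covariate-dependent structure: a random
# low-connectivity background correlation matrix, compound-symmetric
# 15-node regions whose common off-diagonal level is either
# high-connectivity noise (Beta(5,5)) or a covariate-dependent
# noise/Beta mixture, copula-coupled across the 12 (task, repetition)
# scans of a subject, and Pearson correlations of simulated BOLD-like
# time series.

#' Covariate-dependent signal parameter
#'
#' Maps IQ and treatment status to the Beta-shape signal parameter
#' `a = (IQ - 100) * 0.15 + 2 * 1{Treatment} - 2 * 1{Placebo}`, clamped
#' to \[-5.95, 5.95\] so that both parameters of the signal distribution
#' `Beta(7 + a, 7 - a)` stay strictly positive.
#'
#' @param iq Numeric IQ value(s).
#' @param trt Character treatment status: `"Treatment"` or `"Placebo"`.
#' @return Clamped signal parameter(s) in \[-5.95, 5.95\].
#' @export
signal_parameter <- function(iq, trt) {
  raw <- (iq - 100) * 0.15 + 2 * (trt == "Treatment") - 2 * (trt == "Placebo")
  pmin(5.95, pmax(-5.95, raw))
}

#' Simulate subject covariates
#'
#' Fair-coin sex and treatment status; IQ and age drawn from
#' `round(Normal(100, 15^2))`. Sex and age have no effect on the
#' generated networks (null covariates); IQ and treatment drive the
#' signal parameter `a`.
#'
#' @param n_subjects Number of subjects (at least 2).
#' @param seed Optional RNG seed.
#' @return Tibble: `subject`, `SEX`, `TRT`, `AGE`, `IQ`, `a`.
#' @export
simulate_covariates <- function(n_subjects, seed = NULL) {
  if (n_subjects < 2) abort("need at least 2 subjects")
  if (!is.null(seed)) set.seed(seed)
  width <- max(3, nchar(as.character(n_subjects)))
  tibble(
    subject = sprintf("S%0*d", width, seq_len(n_subjects)),
    SEX = sample(c("Female", "Male"), n_subjects, replace = TRUE),
    TRT = sample(c("Placebo", "Treatment"), n_subjects, replace = TRUE),
    AGE = round(rnorm(n_subjects, 100, 15)),
    IQ = round(rnorm(n_subjects, 100, 15))
  ) %>% mutate(a = signal_parameter(.data$IQ, .data$TRT))
}

#' Smooth a correlation matrix to be positive definite
#'
#' Eigenvalue flooring with diagonal rescaling: if the smallest
#' eigenvalue is at least `tol` the input is returned unchanged;
#' otherwise eigenvalues are floored at `tol`, the matrix reconstructed
#' and rescaled back to unit diagonal, repeating (at most 5 times) until
#' the minimum eigenvalue is at least `tol * (1 - 1e-6)`.
#'
#' @param M Symmetric matrix with unit diagonal.
#' @param tol Eigenvalue floor (default `1e-6`).
#' @return A unit-diagonal correlation matrix with minimum eigenvalue at
#'   least `tol * (1 - 1e-6)`.
#' @export
smooth_correlation <- function(M, tol = 1e-6) {
  if (max(abs(M - t(M))) > 1e-8) abort("`M` must be symmetric")
  for (pass in 1:6) {
    e <- eigen(M, symmetric = TRUE)
    if (min(e$values) >= tol * (1 - 1e-6) &&
        (pass > 1 || min(e$values) >= tol)) {
      return(M)
    }
    if (pass == 6) abort("correlation smoothing failed to converge in 5 passes")
    ev <- pmax(e$values, tol)
    M <- e$vectors %*% (ev * t(e$vectors))
    M <- stats::cov2cor(M)
    M <- (M + t(M)) / 2
  }
}

#' Random low-connectivity background correlation matrix
#'
#' Builds the background ("low-connectivity noise") correlation matrix:
#' `Q` a Haar-distributed orthonormal matrix (QR of a Gaussian matrix,
#' via [pracma::randortho()]), `D` diagonal with entries
#' `50 * Beta(34, 2)`, `A = Q' D Q`, standardized to a correlation
#' matrix `B^{-1/2} A B^{-1/2}` with `B = diag(A)`, then smoothed with
#' [smooth_correlation()].
#'
#' @param n_nodes Matrix dimension (at least 2).
#' @param seed Optional RNG seed.
#' @param tol Smoothing tolerance (default `1e-6`).
#' @return Unit-diagonal SPD correlation matrix.
#' @export
make_sigma1 <- function(n_nodes, seed = NULL, tol = 1e-6) {
  if (n_nodes < 2) abort("need at least 2 nodes")
  if (!is.null(seed)) set.seed(seed)
  Q <- pracma::randortho(n_nodes, type = "orthonormal")
  d <- 50 * rbeta(n_nodes, 34, 2)
  A <- crossprod(Q, d * Q)
  b <- diag(A)
  S <- A / sqrt(outer(b, b))
  diag(S) <- 1
  S <- (S + t(S)) / 2
  smooth_correlation(S, tol)
}

#' Copula correlation over (task, repetition) scan cells
#'
#' The latent-Gaussian correlation matrix coupling one region's
#' off-diagonal level across a subject's scans: 1 on the diagonal, 0.7
#' between repetitions of the same task, 0.3 between the same repetition
#' of different tasks, 0 elsewhere. Cells are ordered task-major:
#' (task 1, rep 1..n_reps), (task 2, rep 1..n_reps), ...
#'
#' @param n_tasks,n_reps Grid dimensions (defaults 3 and 4).
#' @param within_task,within_rep Correlation levels (defaults 0.7, 0.3).
#' @return `n_tasks * n_reps` square correlation matrix.
#' @export
copula_spec <- function(n_tasks = 3, n_reps = 4,
                        within_task = 0.7, within_rep = 0.3) {
  cells <- expand.grid(rep = seq_len(n_reps), task = seq_len(n_tasks))
  cells <- cells[order(cells$task, cells$rep), ]
  m <- nrow(cells)
  C <- matrix(0, m, m)
  same_task <- outer(cells$task, cells$task, "==")
  same_rep <- outer(cells$rep, cells$rep, "==")
  C[same_task & !same_rep] <- within_task
  C[!same_task & same_rep] <- within_rep
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort("copula correlation matrix is not positive semi-definite")
  }
  C
}

#' Region layout: which 15-node regions carry covariate signal per task
#'
#' Each task has `n_regions` contiguous regions of `region_size` nodes
#' at the start of the node ordering. Task `j` has its last `j` regions
#' covariate-dependent ("signal") and the rest high-connectivity
#' "noise": task 1 has regions (x, y) noise and z signal, task 2 has x
#' noise and (y, z) signal, task 3 has all three signal.
#'
#' @param n_tasks Number of tasks (default 3).
#' @param n_regions Regions per task (default 3).
#' @param region_size Nodes per region (default 15).
#' @return Tibble: `task` (index), `region`, `role`, and node index
#'   bounds `from`, `to`.
#' @export
region_layout <- function(n_tasks = 3, n_regions = 3, region_size = 15) {
  grid <- expand.grid(region = seq_len(n_regions), task = seq_len(n_tasks))
  tibble(
    task = grid$task,
    region = grid$region,
    role = ifelse(grid$region > n_regions - pmin(grid$task, n_regions),
                  "signal", "noise"),
    from = (grid$region - 1) * region_size + 1,
    to = grid$region * region_size
  )
}

# Inverse ECDF of the absolute off-diagonal pool of the background
# correlation matrix.
pool_quantile <- function(pool_sorted, u) {
  pool_sorted[pmax(1L, ceiling(u * length(pool_sorted)))]
}

#' Draw copula-coupled region correlation levels for one subject region
#'
#' Draws the common off-diagonal correlation level of one 15-node region
#' for each of a subject's `n_tasks * n_reps` scans. A latent Gaussian
#' vector from [copula_spec()] is mapped to uniforms; each scan's level
#' is then the corresponding quantile of that scan's marginal: for tasks
#' where the region is "noise", `Beta(5, 5)`; where it is "signal", the
#' mixture `(1 - s) * Fpool^{-1}(u) + s * FBeta(7+a, 7-a)^{-1}(u)` with
#' `Fpool` the ECDF of the absolute off-diagonal background pool. The
#' default comonotone combination applies the shared quantile through
#' both component inverse CDFs, preserving the copula's rank-correlation
#' structure; `mixing = "mixture"` instead inverts the mixture CDF
#' itself.
#'
#' @param a Subject signal parameter from [signal_parameter()].
#' @param roles Character vector, one role per task (`"noise"` or
#'   `"signal"`), for this region.
#' @param signal Signal fraction `s` in \[0, 1\].
#' @param copula Copula correlation matrix from [copula_spec()].
#' @param pool Sorted absolute off-diagonal values of the background
#'   correlation matrix.
#' @param n_reps Repetitions per task.
#' @param mixing `"comonotone"` (default) or `"mixture"`.
#' @param seed Optional RNG seed.
#' @return `n_tasks` x `n_reps` matrix of correlation levels.
#' @export
draw_region_levels <- function(a, roles, signal, copula, pool,
                               n_reps = 4, mixing = c("comonotone", "mixture"),
                               seed = NULL) {
  mixing <- match.arg(mixing)
  if (signal < 0 || signal > 1) abort("`signal` must be in [0, 1]")
  n_tasks <- length(roles)
  if (nrow(copula) != n_tasks * n_reps) {
    abort("copula dimension does not match n_tasks * n_reps")
  }
  if (!is.null(seed)) set.seed(seed)
  e <- eigen(copula, symmetric = TRUE)
  root <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  z <- drop(rnorm(nrow(copula)) %*% root)
  u <- pnorm(z)
  r <- numeric(length(u))
  for (j in seq_len(n_tasks)) {
    cells <- (j - 1) * n_reps + seq_len(n_reps)
    uu <- u[cells]
    r[cells] <- if (roles[j] == "noise") {
      qbeta(uu, 5, 5)
    } else if (mixing == "comonotone") {
      (1 - signal) * pool_quantile(pool, uu) +
        signal * qbeta(uu, 7 + a, 7 - a)
    } else {
      vapply(uu, function(ui) mixture_quantile(ui, signal, a, pool),
             numeric(1))
    }
  }
  matrix(r, nrow = n_tasks, ncol = n_reps, byrow = TRUE)
}

# Numeric inversion of the mixture CDF
# F(x) = (1 - s) Fpool(x) + s FBeta(x; 7+a, 7-a).
mixture_quantile <- function(u, s, a, pool) {
  f <- function(x) {
    (1 - s) * mean(pool <= x) + s * pbeta(x, 7 + a, 7 - a) - u
  }
  stats::uniroot(f, c(0, 1 - 1e-12), tol = 1e-10)$root
}

# Compound-symmetric correlation block: unit diagonal, constant
# off-diagonal r.
cs_block <- function(size, r) {
  if (abs(r) >= 1) abort("region correlation level |r| >= 1: block not PD")
  if (r <= -1 / (size - 1)) abort("region correlation level makes block non-PD")
  M <- matrix(r, size, size)
  diag(M) <- 1
  M
}

#' Simulate one scan's connection matrix
#'
#' Draws `n_time` points of a zero-mean Gaussian time series with the
#' background covariance, overwrites each region's series with
#' independent draws from its compound-symmetric block (unit diagonal,
#' constant off-diagonal equal to that scan's region level), computes
#' the sample Pearson correlation matrix and smooths it to SPD.
#'
#' @param sigma1_chol Upper-triangular Cholesky factor of the background
#'   correlation matrix.
#' @param region_levels Numeric vector: one correlation level per
#'   region, in region order.
#' @param region_size Nodes per region.
#' @param n_time Number of time points.
#' @param tol Smoothing tolerance.
#' @param seed Optional RNG seed.
#' @return SPD correlation matrix (`nrow(sigma1_chol)` square).
#' @export
simulate_scan <- function(sigma1_chol, region_levels, region_size = 15,
                          n_time = 2500, tol = 1e-6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_nodes <- ncol(sigma1_chol)
  Y <- matrix(rnorm(n_time * n_nodes), n_time) %*% sigma1_chol
  for (g in seq_along(region_levels)) {
    idx <- (g - 1) * region_size + seq_len(region_size)
    block_chol <- chol(cs_block(region_size, region_levels[g]))
    Y[, idx] <- matrix(rnorm(n_time * region_size), n_time) %*% block_chol
  }
  C <- cor(Y)
  smooth_correlation(C, tol)
}

#' Simulate a full multitask, multisession network dataset
#'
#' Generates covariates and all `n_subjects * n_tasks * n_reps`
#' connection matrices under the covariate-dependent SPD simulation
#' model. Seeding is hierarchical (master seed, then per-subject region
#' streams, then per-scan streams) so any single scan is reproducible in
#' isolation.
#'
#' @param n_subjects,n_nodes,n_tasks,n_reps,n_time Study dimensions.
#'   Defaults are the full-scale design: 100 subjects, 268 nodes, 3
#'   tasks, 4 repetitions, 2500 time points.
#' @param signal Signal fraction `s` in \[0, 1\] (default 0: null data).
#' @param region_size,n_regions Region geometry (defaults 15 and 3).
#' @param tol Correlation smoothing tolerance (default `1e-6`).
#' @param mixing Mixture mechanism for signal regions; see
#'   [draw_region_levels()].
#' @param seed Master seed (required for reproducibility; defaults to a
#'   random draw).
#' @return A `bantor_sim` list: `scans` (tibble with `subject`, `task`,
#'   `rep`, `matrix` list-column), `covariates`, `sigma1`, `layout`,
#'   `config`.
#' @export
simulate_dataset <- function(n_subjects = 100, n_nodes = 268, n_tasks = 3,
                             n_reps = 4, n_time = 2500, signal = 0,
                             region_size = 15, n_regions = 3, tol = 1e-6,
                             mixing = c("comonotone", "mixture"),
                             seed = NULL) {
  mixing <- match.arg(mixing)
  if (signal < 0 || signal > 1) abort("`signal` must be in [0, 1]")
  if (n_nodes <= n_regions * region_size) {
    abort("n_nodes must exceed n_regions * region_size")
  }
  if (is.null(seed)) seed <- sample.int(2147483646, 1)

  covariates <- simulate_covariates(n_subjects, seed = derive_seed(seed, 1))
  sigma1 <- make_sigma1(n_nodes, seed = derive_seed(seed, 2), tol = tol)
  pool <- sort(abs(upper_edges(sigma1)))
  layout <- region_layout(n_tasks, n_regions, region_size)
  copula <- copula_spec(n_tasks, n_reps)
  s1_chol <- chol(sigma1)

  scans <- vector("list", n_subjects * n_tasks * n_reps)
  keys <- vector("list", length(scans))
  row <- 0
  for (i in seq_len(n_subjects)) {
    a_i <- covariates$a[i]
    levels_by_region <- lapply(seq_len(n_regions), function(g) {
      roles <- layout$role[layout$region == g][order(layout$task[layout$region == g])]
      draw_region_levels(a_i, roles, signal, copula, pool,
                         n_reps = n_reps, mixing = mixing,
                         seed = derive_seed(seed, 3, i, g))
    })
    for (j in seq_len(n_tasks)) {
      for (k in seq_len(n_reps)) {
        r_jk <- vapply(levels_by_region, function(L) L[j, k], numeric(1))
        C <- simulate_scan(s1_chol, r_jk, region_size = region_size,
                           n_time = n_time, tol = tol,
                           seed = derive_seed(seed, 4, i, j, k))
        row <- row + 1
        scans[[row]] <- C
        keys[[row]] <- list(subject = covariates$subject[i],
                            task = paste0("T", j), rep = k)
      }
    }
  }
  keys <- bind_rows(lapply(keys, as_tibble))
  structure(
    list(scans = mutate(keys, matrix = scans),
         covariates = covariates,
         sigma1 = sigma1,
         layout = layout,
         config = list(n_subjects = n_subjects, n_nodes = n_nodes,
                       n_tasks = n_tasks, n_reps = n_reps, n_time = n_time,
                       signal = signal, region_size = region_size,
                       n_regions = n_regions, tol = tol, mixing = mixing,
                       seed = seed)),
    class = "bantor_sim")
}

#' @export
#' @method print bantor_sim
print.bantor_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<bantor_sim: %d subjects x %d tasks x %d reps, %d nodes, signal %.0f%%, seed %d>\n",
    cfg$n_subjects, cfg$n_tasks, cfg$n_reps, cfg$n_nodes,
    100 * cfg$signal, cfg$seed))
  invisible(x)
}

#' Fraction of edges interior to covariate-dependent regions
#'
#' Analytic count of upper-triangle edges lying inside signal regions,
#' per task: a task with `m` signal regions of 15 nodes has
#' `m * choose(15, 2)` covariate-dependent edges out of
#' `choose(n_nodes, 2)`. At 268 nodes this gives 105/35778, 210/35778
#' and 315/35778 for tasks 1-3, i.e. roughly 0.3%, 0.6% and 0.9%.
#'
#' @inheritParams region_layout
#' @param n_nodes Total nodes (default 268).
#' @return Tibble: `task`, `n_signal_edges`, `n_edges`, `fraction`.
#' @export
signal_edge_fraction <- function(n_nodes = 268, n_tasks = 3, n_regions = 3,
                                 region_size = 15) {
  lay <- region_layout(n_tasks, n_regions, region_size)
  per_region <- choose(region_size, 2)
  n_edges <- choose(n_nodes, 2)
  lay %>%
    group_by(task = .data$task) %>%
    summarise(n_signal_edges = sum(.data$role == "signal") * per_region,
              .groups = "drop") %>%
    mutate(n_edges = n_edges,
           fraction = .data$n_signal_edges / n_edges)
}
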