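# Shared fixtures: all built in code at test time.

# Random SPD correlation matrix (well-conditioned) of dimension n.
rand_spd_cor <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(rnorm(n * 2 * n), 2 * n, n)
  S <- crossprod(W) / (2 * n)
  stats::cov2cor(S)
}

# Random symmetric "connection matrix" with entries in [-1, 1] and unit
# diagonal (not necessarily PD).
rand_conn <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- matrix(0, n, n)
  C[upper.tri(C)] <- runif(n * (n - 1) / 2, -0.9, 0.9)
  C <- C + t(C)
  diag(C) <- 1
  C
}

# Scan table of random connection matrices.
toy_scans <- function(n_subjects, n_tasks, n_reps, n_nodes, seed = 1,
                      spd = FALSE) {
  set.seed(seed)
  grid <- expand.grid(rep = seq_len(n_reps), task = seq_len(n_tasks),
                      subject = seq_len(n_subjects))
  mats <- lapply(seq_len(nrow(grid)), function(i) {
    if (spd) rand_spd_cor(n_nodes) else rand_conn(n_nodes)
  })
  tibble::tibble(subject = sprintf("S%02d", grid$subject),
                 task = paste0("T", grid$task),
                 rep = grid$rep,
                 matrix = mats)
}

# Covariate table matching toy_scans subject ids.
toy_covariates <- function(n_subjects, seed = 2) {
  set.seed(seed)
  tibble::tibble(
    subject = sprintf("S%02d", seq_len(n_subjects)),
    SEX = sample(c("Female", "Male"), n_subjects, replace = TRUE),
    TRT = sample(c("Placebo", "Treatment"), n_subjects, replace = TRUE),
    AGE = round(rnorm(n_subjects, 100, 15)),
    IQ = round(rnorm(n_subjects, 100, 15))
  )
}

# A design built from scratch for a given shape (values drawn iid),
# useful when the response is to be generated directly from the model.
toy_design <- function(n_subjects, n_tasks, n_reps, seed = 3,
                       terms = c("AGE", "SEX", "TRT", "IQ")) {
  scans <- toy_scans(n_subjects, n_tasks, n_reps, 8, seed = seed)
  d <- network_distances(scans, "euclidean")
  build_design(d, toy_covariates(n_subjects, seed = seed + 1), terms = terms)
}

expect_tidy_equal <- function(a, b, tol = 1e-8) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
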