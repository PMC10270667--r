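test_that("signal parameter follows the clamped covariate formula", {
  expect_equal(signal_parameter(100, "Treatment"), 2)
  expect_equal(signal_parameter(100, "Placebo"), -2)
  expect_equal(signal_parameter(70, "Placebo"), -5.95)  # raw -6.5 clamped
  expect_equal(signal_parameter(130, "Treatment"), 5.95) # raw 6.5 clamped
  expect_equal(signal_parameter(110, "Treatment"), 3.5)
})

test_that("covariates reproduce their generating moments and bounds", {
  cov1 <- simulate_covariates(50, seed = 70)
  cov2 <- simulate_covariates(50, seed = 70)
  expect_identical(cov1, cov2)

  big <- simulate_covariates(10000, seed = 71)
  expect_lt(abs(mean(big$IQ) - 100), 0.5)
  expect_lt(abs(sd(big$IQ) - 15), 0.5)
  expect_lt(abs(mean(big$AGE) - 100), 0.5)
  expect_lt(abs(mean(big$SEX == "Male") - 0.5), 0.02)
  expect_true(all(big$a >= -5.95 & big$a <= 5.95))
  expect_true(all(big$IQ == round(big$IQ)))
})

test_that("correlation smoothing floors eigenvalues and keeps unit diagonal", {
  S <- rand_spd_cor(6, seed = 72)
  expect_identical(smooth_correlation(S, 1e-6), S) # already PD: unchanged

  M <- matrix(0.99, 3, 3); diag(M) <- 1
  M[1, 2] <- M[2, 1] <- -0.9 # indefinite
  out <- smooth_correlation(M, 1e-6)
  expect_equal(diag(out), rep(1, 3))
  expect_gte(min(eigen(out, symmetric = TRUE)$values), 1e-6 * (1 - 1e-6))

  v <- c(1, -0.5, 0.3, 0.8)
  R1 <- outer(v, v); diag(R1) <- 1 # rank-deficient correlation-like
  out2 <- smooth_correlation(R1, 1e-6)
  expect_gte(min(eigen(out2, symmetric = TRUE)$values), 1e-6 * (1 - 1e-6))
  expect_error(smooth_correlation(matrix(c(1, 0.2, 0.4, 1), 2), 1e-6),
               "symmetric")
})

test_that("background correlation matrix is a valid SPD correlation matrix", {
  S1 <- make_sigma1(40, seed = 73)
  expect_equal(diag(S1), rep(1, 40))
  expect_true(isSymmetric(S1))
  expect_gte(min(eigen(S1, symmetric = TRUE)$values), 1e-6 * (1 - 1e-6))
  expect_identical(S1, make_sigma1(40, seed = 73))
})

test_that("background off-diagonals match an independent re-implementation", {
  # independent construction: QR of a Gaussian matrix with sign fix,
  # D ~ 50 Beta(34,2), correlation standardization
  indep_sigma1 <- function(n, seed) {
    set.seed(seed)
    Z <- matrix(rnorm(n * n), n)
    qrz <- qr(Z)
    Q <- qr.Q(qrz) %*% diag(sign(diag(qr.R(qrz))))
    d <- 50 * rbeta(n, 34, 2)
    A <- t(Q) %*% diag(d) %*% Q
    b <- diag(A)
    A / sqrt(outer(b, b))
  }
  pool_mine <- abs(upper_edges(make_sigma1(60, seed = 74)))
  pool_ind <- abs(upper_edges(indep_sigma1(60, seed = 75)))
  expect_lt(abs(mean(pool_mine) - mean(pool_ind)), 0.02)
  expect_lt(abs(sd(pool_mine) - sd(pool_ind)), 0.02)
  expect_lt(abs(mean(pool_mine)), 0.15) # concentrated near zero
})

test_that("copula correlation matrix matches the scan-cell layout", {
  C <- copula_spec(3, 4)
  expect_equal(dim(C), c(12, 12))
  expect_equal(diag(C), rep(1, 12))
  expect_equal(C[1, 2], 0.7)  # task 1 rep 1 vs task 1 rep 2
  expect_equal(C[1, 5], 0.3)  # task 1 rep 1 vs task 2 rep 1
  expect_equal(C[1, 6], 0)    # task 1 rep 1 vs task 2 rep 2
  expect_equal(C[5, 9], 0.3)  # task 2 rep 1 vs task 3 rep 1
  # the 0.7 / 0.3 structure is exactly singular (1 - 0.7 - 0.3 = 0):
  # positive semi-definite, handled by an eigendecomposition square root
  expect_gte(min(eigen(C, symmetric = TRUE)$values), -1e-8)
})

test_that("region layout assigns signal roles per task", {
  lay <- region_layout(3, 3, 15)
  roles <- function(tk) lay$role[lay$task == tk]
  expect_equal(roles(1), c("noise", "noise", "signal"))
  expect_equal(roles(2), c("noise", "signal", "signal"))
  expect_equal(roles(3), c("signal", "signal", "signal"))
  expect_equal(lay$from[lay$region == 2][1], 16)
  expect_equal(lay$to[lay$region == 3][1], 45)
})

test_that("signal-edge fractions match the analytic counts", {
  fr <- signal_edge_fraction(268, 3, 3, 15)
  expect_equal(fr$n_signal_edges, c(105, 210, 315))
  expect_equal(fr$n_edges, rep(35778, 3))
  expect_equal(round(100 * fr$fraction, 1), c(0.3, 0.6, 0.9))
})

test_that("region levels at zero signal reproduce the absolute background pool", {
  S1 <- make_sigma1(60, seed = 76)
  pool <- sort(abs(upper_edges(S1)))
  cop <- copula_spec(3, 4)
  set.seed(77)
  draws <- replicate(450, {
    draw_region_levels(a = 2, roles = c("signal", "signal", "signal"),
                       signal = 0, copula = cop, pool = pool)
  })
  # 450 x 12 = 5400 marginal draws vs the pool itself
  expect_gt(suppressWarnings(
    stats::ks.test(as.numeric(draws), pool))$p.value, 0.01)
})

test_that("region levels at full signal with a = 0 follow Beta(7, 7)", {
  S1 <- make_sigma1(30, seed = 78)
  pool <- sort(abs(upper_edges(S1)))
  cop <- copula_spec(3, 4)
  set.seed(79)
  draws <- as.numeric(replicate(450, {
    draw_region_levels(a = 0, roles = rep("signal", 3), signal = 1,
                       copula = cop, pool = pool)
  }))
  expect_lt(abs(mean(draws) - 0.5), 0.01)      # Beta(7,7) mean
  expect_lt(abs(var(draws) - 0.25 / 15), 0.003) # Beta(7,7) variance
})

test_that("copula rank correlation survives the marginal transforms", {
  S1 <- make_sigma1(30, seed = 80)
  pool <- sort(abs(upper_edges(S1)))
  cop <- copula_spec(3, 4)
  set.seed(81)
  draws <- replicate(2000, {
    L <- draw_region_levels(a = 1, roles = c("noise", "signal", "signal"),
                            signal = 0.5, copula = cop, pool = pool)
    c(L[1, 1], L[1, 2], L[2, 1], L[3, 1])
  })
  # within-task pair (task 1 reps 1-2): latent 0.7 -> Spearman of a
  # monotone transform of a Gaussian pair: 6/pi*asin(0.7/2) ~ 0.688
  rho_wt <- cor(draws[1, ], draws[2, ], method = "spearman")
  expect_lt(abs(rho_wt - 6 / pi * asin(0.7 / 2)), 0.05)
  # within-repetition across tasks: latent 0.3 -> ~ 0.287
  rho_wr <- cor(draws[3, ], draws[4, ], method = "spearman")
  expect_lt(abs(rho_wr - 6 / pi * asin(0.3 / 2)), 0.06)
})

test_that("the mixture-CDF inversion variant matches its defining equation", {
  S1 <- make_sigma1(20, seed = 82)
  pool <- sort(abs(upper_edges(S1)))
  for (u in c(0.1, 0.5, 0.9)) {
    x <- bantor:::mixture_quantile(u, s = 0.4, a = 1.5, pool = pool)
    fmix <- 0.6 * mean(pool <= x) + 0.4 * pbeta(x, 8.5, 5.5)
    expect_lt(abs(fmix - u), 0.02) # ECDF component is a step function
  }
})

test_that("simulated scans carry the requested region correlation levels", {
  set.seed(83)
  S1 <- make_sigma1(40, seed = 83)
  ch <- chol(S1)
  C <- simulate_scan(ch, region_levels = c(0.6, 0.2), region_size = 10,
                     n_time = 2500, seed = 84)
  expect_silent(validate_connection_matrix(C))
  expect_gte(min(eigen(C, symmetric = TRUE)$values), 1e-6 * (1 - 2e-6))
  r1 <- C[1:10, 1:10][upper.tri(diag(10))]
  r2 <- C[11:20, 11:20][upper.tri(diag(10))]
  expect_lt(abs(mean(r1) - 0.6), 0.05)
  expect_lt(abs(mean(r2) - 0.2), 0.05)
  # region-to-remaining correlations average near zero
  expect_lt(abs(mean(C[1:10, 21:40])), 0.05)
  expect_error(simulate_scan(ch, region_levels = 1.2, region_size = 10),
               "not PD|non-PD")
})

test_that("full dataset simulation has the right shape and is reproducible", {
  ds <- simulate_dataset(n_subjects = 4, n_nodes = 20, n_tasks = 3,
                         n_reps = 2, n_time = 80, signal = 0.5,
                         region_size = 4, seed = 85)
  expect_equal(nrow(ds$scans), 4 * 3 * 2)
  expect_equal(nrow(ds$covariates), 4)
  expect_equal(sum(ds$layout$role == "signal" & ds$layout$task == 1), 1)
  expect_equal(sum(ds$layout$role == "signal" & ds$layout$task == 3), 3)
  ds2 <- simulate_dataset(n_subjects = 4, n_nodes = 20, n_tasks = 3,
                          n_reps = 2, n_time = 80, signal = 0.5,
                          region_size = 4, seed = 85)
  expect_identical(ds$scans$matrix, ds2$scans$matrix)
  expect_identical(ds$covariates, ds2$covariates)
  for (m in ds$scans$matrix[1:4]) {
    expect_silent(validate_connection_matrix(m))
  }
  expect_error(simulate_dataset(n_subjects = 4, n_nodes = 10,
                                region_size = 4, seed = 1),
               "exceed")
  expect_error(simulate_dataset(n_subjects = 4, n_nodes = 30,
                                region_size = 4, signal = 1.5, seed = 1),
               "signal")
})
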