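# ---- profiled REML for the crossed dyad-random-intercept model --------------
#
# The 3M_BANTOR model is y = X beta + Z b + e with Z the indicator matrix
# of (dyad, task) groups, b_g ~ N(0, sigma2 * gamma_{task(g)}) and
# e ~ N(0, sigma2 * I). Because the groups partition the rows,
# V0 = I + sum_b gamma_b Z_b Z_b' is block diagonal with analytic
# inverse per group, I - w_g J, w_g = gamma_g / (1 + gamma_g m_g), and
# log|V0| = sum_g log(1 + gamma_g m_g). The GLS normal equations then
# only need X'X, the per-group column sums A = T'X (sparse) and the
# matching y statistics, so one REML evaluation costs a sparse rank
# update plus one dense Cholesky of X'V0^{-1}X — independent of n.
# beta and sigma2 are profiled out; the variance ratios gamma_b are
# optimized by bounded quasi-Newton on the log scale.

reml_prepare <- function(X, group, task_of_group) {
  n <- nrow(X)
  p <- ncol(X)
  group <- as.integer(group)
  n_g <- max(group)
  Tmat <- Matrix::sparseMatrix(i = seq_len(n), j = group, x = 1,
                               dims = c(n, n_g))
  A <- Matrix::crossprod(Tmat, X) # n_g x p group column sums
  list(X = X, n = n, p = p, group = group, n_g = n_g,
       m = tabulate(group, n_g), gtask = as.integer(task_of_group),
       n_tasks = max(as.integer(task_of_group)),
       XtX = as.matrix(Matrix::crossprod(X)), A = A,
       colnames = colnames(X))
}

reml_y_stats <- function(pre, y) {
  list(Xty = as.numeric(Matrix::crossprod(pre$X, y)),
       yty = sum(y * y),
       a_y = as.numeric(rowsum(y, pre$group)))
}

# Determine identifiable columns once by a sequential (order-preserving)
# rank-revealing Cholesky of the GLS crossproduct at a reference gamma:
# a column collinear with earlier columns is dropped, so covariate
# columns (which come first) always survive and the redundancy is
# absorbed by the trailing scan indicators. Covariate inference is
# invariant to this identification choice.
reml_keep_columns <- function(pre, gamma_ref = 0.1) {
  w <- gamma_ref / (1 + gamma_ref * pre$m)
  M <- pre$XtX - as.matrix(Matrix::crossprod(sqrt(w) * pre$A))
  p <- ncol(M)
  tol <- max(diag(M)) * 1e-9
  R <- matrix(0, p, p)
  keep <- integer(0)
  k <- 0
  for (j in seq_len(p)) {
    rj <- if (k > 0) {
      forwardsolve(t(R[seq_len(k), seq_len(k), drop = FALSE]), M[keep, j])
    } else {
      numeric(0)
    }
    dj <- M[j, j] - sum(rj^2)
    if (dj > tol) {
      k <- k + 1
      keep[k] <- j
      if (k > 1) R[seq_len(k - 1), k] <- rj
      R[k, k] <- sqrt(dj)
    }
  }
  keep
}

# Core evaluation at variance ratios `gamma` (one per task): profiled
# beta and sigma2, plus all pieces needed by the criterion and the
# Satterthwaite machinery.
reml_eval <- function(pre, ys, gamma, keep) {
  g_g <- gamma[pre$gtask]
  w <- g_g / (1 + g_g * pre$m)
  Aw <- sqrt(w) * pre$A[, keep, drop = FALSE]
  M <- pre$XtX[keep, keep] - as.matrix(Matrix::crossprod(Aw))
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Xty_v <- ys$Xty[keep] - as.numeric(Matrix::crossprod(
    pre$A[, keep, drop = FALSE], w * ys$a_y))
  yty_v <- ys$yty - sum(w * ys$a_y^2)
  beta <- backsolve(ch, forwardsolve(t(ch), Xty_v))
  rss <- max(yty_v - sum(Xty_v * beta), 1e-300) # y' P0 y
  r <- length(keep)
  logdet_v0 <- sum(log1p(g_g * pre$m))
  logdet_m <- 2 * sum(log(diag(ch)))
  sigma2 <- rss / (pre$n - r)
  list(gamma = gamma, w = w, M = M, chol = ch, beta = beta, rss = rss,
       sigma2 = sigma2, logdet_v0 = logdet_v0, logdet_m = logdet_m,
       keep = keep, rank = r)
}

# -2 * restricted log-likelihood, unprofiled in sigma2 (used for the
# observed-information Hessian) or profiled (sigma2 = NULL).
reml_neg2ll <- function(ev, n, sigma2 = NULL) {
  r <- ev$rank
  if (is.null(sigma2)) sigma2 <- ev$rss / (n - r)
  (n - r) * log(2 * pi) + (n - r) * log(sigma2) +
    ev$logdet_v0 + ev$logdet_m + ev$rss / sigma2
}

reml_optimize <- function(pre, ys, keep, start = NULL,
                          lower_log = log(1e-10), rel_tol = 1e-8,
                          max_iter = 500) {
  B <- pre$n_tasks
  if (is.null(start)) start <- rep(0.05, B)
  objective <- function(phi) {
    ev <- reml_eval(pre, ys, exp(phi), keep)
    if (is.null(ev)) return(1e10)
    reml_neg2ll(ev, pre$n)
  }
  opt <- stats::nlminb(log(pmax(start, 1e-8)), objective,
                       lower = lower_log, upper = log(1e6),
                       control = list(rel.tol = rel_tol, x.tol = 1e-12,
                                      iter.max = max_iter,
                                      eval.max = 4 * max_iter))
  if (opt$convergence != 0 &&
      !grepl("relative convergence|both X|singular convergence",
             opt$message %||% "")) {
    abort(sprintf("REML optimization did not converge: %s (objective %.6g)",
                  opt$message, opt$objective))
  }
  gamma <- exp(opt$par)
  gamma[gamma <= 1.5e-10] <- 0 # boundary: treat floor hits as zero
  list(gamma = gamma, objective = opt$objective,
       iterations = opt$iterations, converged = TRUE,
       boundary = any(gamma == 0))
}

# Analytic observed-information Hessian of -2lR in theta =
# (gamma_1..gamma_B, sigma2). Because the random-effect groups of
# different tasks are disjoint and V0 is block diagonal by group, all
# the trace terms reduce to per-group scalars plus small dense solves
# against the Cholesky of M = X'V0^{-1}X. With c_g = 1/(1 + gamma_g
# m_g), e_g = c_g (group residual sum), a_g the group column sums:
#   d2 log|V0|        = -diag over b of sum m^2 c^2
#   d2 log|M|  (b,c)  = [b == c] 2 sum m c^3 h_g - tr(W_b W_c)
#   d2 (rss)   (b,c)  = 2 ([b == c] sum m c e^2 - z_b' M^{-1} z_c)
# with h_g = a_g' M^{-1} a_g, W_b = M^{-1} dM/dgamma_b and
# z_b = sum_{g in b} c_g^2 e_g... a_g (see below).
reml_information <- function(pre, ev, e_g) {
  B <- pre$n_tasks
  g_g <- ev$gamma[pre$gtask]
  m <- pre$m
  cg <- 1 / (1 + g_g * m)
  Ak <- pre$A[, ev$keep, drop = FALSE]
  # St[, g] = R^{-T} a_g ; h_g = |St[, g]|^2
  St <- forwardsolve(t(ev$chol), t(as.matrix(Ak)))
  h_g <- colSums(St^2)
  sigma2 <- ev$sigma2
  n <- pre$n
  r <- ev$rank

  # W_b = M^{-1} dM/dgamma_b, dM/dgamma_b = -sum_{g in b} c^2 a a'
  W <- vector("list", B)
  Z <- matrix(0, r, B) # z_b = Ak' (c^2 e)_b per task
  for (b in seq_len(B)) {
    rows <- which(pre$gtask == b)
    Mb <- -crossprod(sqrt(cg[rows]^2) * as.matrix(Ak[rows, , drop = FALSE]))
    W[[b]] <- backsolve(ev$chol, forwardsolve(t(ev$chol), Mb))
    Z[, b] <- as.numeric(Matrix::crossprod(Ak[rows, , drop = FALSE],
                                           cg[rows] * e_g[rows]))
  }
  MinvZ <- backsolve(ev$chol, forwardsolve(t(ev$chol), Z))
  H <- matrix(0, B + 1, B + 1)
  rss <- ev$rss
  for (b in seq_len(B)) {
    rows <- which(pre$gtask == b)
    for (cc in b:B) {
      d2m <- -sum(W[[b]] * t(W[[cc]]))
      d2rss <- -2 * sum(Z[, b] * MinvZ[, cc])
      if (cc == b) {
        d2m <- d2m + 2 * sum(m[rows] * cg[rows]^3 * h_g[rows])
        d2rss <- d2rss + 2 * sum(m[rows] * cg[rows] * e_g[rows]^2)
        H[b, b] <- -sum(m[rows]^2 * cg[rows]^2) + d2m + d2rss / sigma2
      } else {
        H[b, cc] <- H[cc, b] <- d2m + d2rss / sigma2
      }
    }
    H[b, B + 1] <- H[B + 1, b] <- sum(e_g[rows]^2) / sigma2^2
  }
  H[B + 1, B + 1] <- -(n - r) / sigma2^2 + 2 * rss / sigma2^3
  H
}

# Satterthwaite df for each requested coefficient: df = 2 (C_jj)^2 /
# (d' V d) with C the fixed-effect covariance at the REML optimum, d the
# analytic gradient of C_jj in theta = (gamma_1..gamma_B, sigma2)
# (dM/dgamma_b = -A_b' diag(c^2) A_b), and V twice the inverse of the
# analytic observed-information Hessian above.
reml_satterthwaite <- function(pre, ys, ev, sel) {
  B <- pre$n_tasks
  k <- length(sel)
  U <- backsolve(ev$chol, forwardsolve(t(ev$chol),
                                       diag(ev$rank)[, sel, drop = FALSE]))
  cjj <- ev$sigma2 * diag(as.matrix(U[sel, , drop = FALSE]))
  S <- as.matrix(pre$A[, ev$keep, drop = FALSE] %*% U) # n_g x k
  g_g <- ev$gamma[pre$gtask]
  cg2 <- 1 / (1 + g_g * pre$m)^2
  D <- matrix(0, B + 1, k) # gradient of C_jj per theta component
  for (b in seq_len(B)) {
    rows <- pre$gtask == b
    D[b, ] <- ev$sigma2 * colSums(cg2[rows] * S[rows, , drop = FALSE]^2)
  }
  D[B + 1, ] <- cjj / ev$sigma2

  # group residuals e_g = c_g (a_y - A beta)_g
  resid_g <- ys$a_y - as.numeric(pre$A[, ev$keep, drop = FALSE] %*% ev$beta)
  cg <- 1 / (1 + g_g * pre$m)
  e_g <- cg * resid_g
  H <- reml_information(pre, ev, e_g)
  V <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(V)) { # boundary/singular information: clamp via eigen
    e <- eigen((H + t(H)) / 2, symmetric = TRUE)
    ev_inv <- ifelse(abs(e$values) > 1e-10 * max(abs(e$values)),
                     1 / e$values, 0)
    V <- 2 * e$vectors %*% (ev_inv * t(e$vectors))
  }
  denom <- colSums(D * (V %*% D))
  df <- ifelse(denom > 0, 2 * cjj^2 / denom, pre$n - ev$rank)
  structure(pmin(pmax(df, 1), pre$n - ev$rank), vcov_theta = V)
}

# Analytic gradient of the profiled -2lR in gamma (envelope theorem:
# the partial in gamma at sigma2 = sigma2hat(gamma) is the total
# derivative): dF/dgamma_b = sum_{g in b} [m c - c^2 h_g - e_g^2 /
# sigma2].
reml_gradient <- function(pre, ev, e_g) {
  g_g <- ev$gamma[pre$gtask]
  cg <- 1 / (1 + g_g * pre$m)
  Ak <- pre$A[, ev$keep, drop = FALSE]
  St <- forwardsolve(t(ev$chol), t(as.matrix(Ak)))
  h_g <- colSums(St^2)
  per_g <- pre$m * cg - cg^2 * h_g - e_g^2 / ev$sigma2
  as.numeric(rowsum(per_g, pre$gtask))
}

reml_group_resid <- function(pre, ys, ev) {
  g_g <- ev$gamma[pre$gtask]
  cg <- 1 / (1 + g_g * pre$m)
  cg * (ys$a_y - as.numeric(pre$A[, ev$keep, drop = FALSE] %*% ev$beta))
}

# Newton polish of interior variance ratios using the analytic gradient
# and the profiled analytic Hessian (the full observed information with
# the sigma2 row/column profiled out). Boundary components (gamma = 0
# with outward-pointing gradient) are left pinned.
reml_polish <- function(pre, ys, ev, keep, max_steps = 5, tol = 1e-11) {
  B <- pre$n_tasks
  f0 <- reml_neg2ll(ev, pre$n)
  for (step in seq_len(max_steps)) {
    e_g <- reml_group_resid(pre, ys, ev)
    grad <- reml_gradient(pre, ev, e_g)
    interior <- ev$gamma > 0 | grad < 0
    if (!any(interior) || max(abs(grad[interior])) < tol * pre$n) break
    H <- reml_information(pre, ev, e_g)
    Hp <- H[seq_len(B), seq_len(B), drop = FALSE] -
      tcrossprod(H[seq_len(B), B + 1]) / H[B + 1, B + 1]
    ii <- which(interior)
    delta <- tryCatch(
      solve(Hp[ii, ii, drop = FALSE], grad[ii]),
      error = function(e) NULL)
    if (is.null(delta)) break
    gnew <- ev$gamma
    step_scale <- 1
    improved <- FALSE
    for (ls in 1:4) {
      gnew[ii] <- pmax(ev$gamma[ii] - step_scale * delta, 0)
      ev2 <- reml_eval(pre, ys, gnew, keep)
      if (!is.null(ev2) && reml_neg2ll(ev2, pre$n) <= f0 + 1e-12) {
        ev <- ev2
        f0 <- reml_neg2ll(ev2, pre$n)
        improved <- TRUE
        break
      }
      step_scale <- step_scale / 4
    }
    if (!improved) break
  }
  ev
}

fd_hessian <- function(f, x, h) {
  q <- length(x)
  H <- matrix(NA_real_, q, q)
  f0 <- f(x)
  fp <- numeric(q)
  fm <- numeric(q)
  for (i in seq_len(q)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    fp[i] <- f(xp); fm[i] <- f(xm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  for (i in seq_len(q - 1)) {
    for (j in (i + 1):q) {
      xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
      xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
      H[i, j] <- H[j, i] <-
        (f(xpp) - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + f(xmm)) /
        (2 * h[i] * h[j])
    }
  }
  H
}

# Full solve for one response vector against a prepared structure.
reml_solve <- function(pre, y, keep = NULL, start = NULL,
                       satterthwaite = TRUE, sel = NULL) {
  ys <- reml_y_stats(pre, y)
  if (is.null(keep)) keep <- reml_keep_columns(pre)
  opt <- reml_optimize(pre, ys, keep, start = start)
  ev <- reml_eval(pre, ys, opt$gamma, keep)
  ev <- reml_polish(pre, ys, ev, keep)
  opt$gamma <- ev$gamma
  opt$boundary <- any(ev$gamma == 0)
  opt$objective <- reml_neg2ll(ev, pre$n)
  grad_norm <- max(abs(reml_gradient(pre, ev,
                                     reml_group_resid(pre, ys, ev))))
  se <- sqrt(ev$sigma2 * diag(backsolve(
    ev$chol, forwardsolve(t(ev$chol), diag(ev$rank)))))
  names(ev$beta) <- pre$colnames[keep]
  if (is.null(sel)) sel <- seq_along(keep)
  vcov_theta <- NULL
  df <- if (satterthwaite) {
    d <- reml_satterthwaite(pre, ys, ev, sel)
    vcov_theta <- attr(d, "vcov_theta")
    as.numeric(d)
  } else {
    rep(pre$n - ev$rank, length(sel))
  }
  tstat <- ev$beta[sel] / se[sel]
  list(beta = ev$beta, se = stats::setNames(se, pre$colnames[keep]),
       sel = sel, df = df,
       statistic = unname(tstat),
       p.value = unname(2 * pt(-abs(tstat), df)),
       gamma = opt$gamma, sigma2 = ev$sigma2,
       g = opt$gamma * ev$sigma2,
       logLik = -0.5 * opt$objective,
       objective = opt$objective,
       iterations = opt$iterations, grad_norm = grad_norm,
       vcov_theta = vcov_theta,
       boundary = opt$boundary, converged = opt$converged,
       keep = keep, rank = ev$rank, n = pre$n)
}
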