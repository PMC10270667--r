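# ---- model fitting: F test, F test with scan-level effects, 3M_BANTOR ------

# Shared model-frame construction for the lm-based fits. Returns a data
# frame with the response, task factor, regressors and (optionally) the
# scan-indicator matrix column `SCAN` (two 1s per row, one for each scan
# in the pair), plus the fixed-effects formula RHS.
prepare_fit <- function(design, scan_effects) {
  if (!inherits(design, "bantor_design")) {
    abort("`design` must come from build_design()")
  }
  terms <- attr(design, "terms")
  intercept <- attr(design, "intercept")
  df <- data.frame(distance = design$distance,
                   task = factor(design$task),
                   dyad = factor(design$dyad),
                   check.names = FALSE)
  for (tm in terms) df[[tm]] <- design[[tm]]
  task_levels <- levels(df$task)
  # explicit numeric task dummies (a one-level factor cannot be used in
  # an interaction, and dummy columns keep coefficient names stable)
  dum <- paste0("task", task_levels)
  for (b in seq_along(task_levels)) {
    df[[dum[b]]] <- as.numeric(df$task == task_levels[b])
  }
  bt <- function(x) paste0("`", x, "`")
  cov_block <- paste(
    unlist(lapply(terms, function(tm) paste0(bt(dum), ":", bt(tm)))),
    collapse = " + ")
  rhs <- switch(intercept,
    task = paste("0 +", paste(bt(dum), collapse = " + "), "+", cov_block),
    global = paste("1 +", cov_block),
    none = paste("0 +", cov_block)
  )
  scan_levels <- NULL
  if (scan_effects) {
    scan_levels <- sort(unique(c(design$scan1, design$scan2)))
    S <- matrix(0, nrow(design), length(scan_levels),
                dimnames = list(NULL, scan_levels))
    S[cbind(seq_len(nrow(design)), match(design$scan1, scan_levels))] <- 1
    S[cbind(seq_len(nrow(design)), match(design$scan2, scan_levels))] <- 1
    df$SCAN <- S
    rhs <- paste(rhs, "+ SCAN")
  }
  list(df = df, rhs = rhs, terms = terms, task_levels = task_levels,
       scan_levels = scan_levels, intercept = intercept)
}

# Sparse fixed-effects design for the mixed model: per-task intercepts,
# per-task covariate-difference columns, then scan indicators. Column
# names mirror the lm naming so downstream parsing is shared.
build_sparse_X <- function(design, terms, intercept, scan_effects = TRUE) {
  n <- nrow(design)
  task <- as.character(design$task)
  task_levels <- sort(unique(task))
  ti <- match(task, task_levels)
  ii <- list(); jj <- list(); xx <- list()
  nms <- character(0)
  col <- 0
  add_col <- function(rows, vals, name) {
    col <<- col + 1
    ii[[col]] <<- rows
    jj[[col]] <<- rep.int(col, length(rows))
    xx[[col]] <<- vals
    nms[col] <<- name
  }
  if (intercept == "global") {
    add_col(seq_len(n), rep(1, n), "(Intercept)")
  }
  if (intercept == "task") {
    for (b in seq_along(task_levels)) {
      rows <- which(ti == b)
      add_col(rows, rep(1, length(rows)), paste0("task", task_levels[b]))
    }
  }
  for (tm in terms) {
    v <- design[[tm]]
    for (b in seq_along(task_levels)) {
      rows <- which(ti == b)
      add_col(rows, v[rows], paste0("task", task_levels[b], ":", tm))
    }
  }
  scan_levels <- NULL
  if (scan_effects) {
    scan_levels <- sort(unique(c(design$scan1, design$scan2)))
    for (sc in scan_levels) {
      rows <- which(design$scan1 == sc | design$scan2 == sc)
      add_col(rows, rep(1, length(rows)), paste0("SCAN", sc))
    }
  }
  X <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, col))
  colnames(X) <- nms
  list(X = X, task_levels = task_levels, scan_levels = scan_levels)
}

new_bantor_fit <- function(method, fit, pf, note = NULL, degenerate = FALSE,
                           varcomp = NULL, table = NULL, scan_effects = NULL,
                           reml = NULL) {
  structure(list(method = method, fit = fit, terms = pf$terms,
                 task_levels = pf$task_levels, intercept = pf$intercept,
                 scan_levels = pf$scan_levels, note = note,
                 degenerate = degenerate, varcomp = varcomp,
                 table = table, scan_effects = scan_effects, reml = reml),
            class = "bantor_fit")
}

#' Standard F test on the pairwise distance design
#'
#' Ordinary least squares of distances on covariate-difference
#' regressors with per-task coefficient blocks. Because rows sharing a
#' subject are correlated, this test is anticonservative under repeated
#' measures; it is provided as a comparison baseline.
#'
#' @param design A [build_design()] table.
#' @return A `bantor_fit` object; see [tidy.bantor_fit()].
#' @export
fit_f_test <- function(design) {
  pf <- prepare_fit(design, scan_effects = FALSE)
  fit <- lm(as.formula(paste("distance ~", pf$rhs)), data = pf$df)
  check_cov_rank(fit)
  new_bantor_fit("f_test", fit, pf,
                 note = "anticonservative under repeated measures")
}

#' F test with scan-level fixed effects
#'
#' Least squares with one fixed indicator per scan appended to the
#' covariate design, absorbing scan-specific distance shifts. Redundant
#' indicator columns (the scan indicators are collinear with the task
#' intercepts) are resolved by pivoted rank identification; covariate
#' inference is invariant to which columns are dropped.
#'
#' @inheritParams fit_f_test
#' @return A `bantor_fit` object.
#' @export
fit_f_test_sle <- function(design) {
  pf <- prepare_fit(design, scan_effects = TRUE)
  fit <- lm(as.formula(paste("distance ~", pf$rhs)), data = pf$df)
  check_cov_rank(fit)
  new_bantor_fit("f_test_sle", fit, pf,
                 note = "repeated within-task comparisons remain correlated")
}

# A covariate column made NA by pivoting means it is collinear with the
# scan indicators (scan columns are ordered last so they absorb the
# redundancy first); that is a design error worth naming.
check_cov_rank <- function(fit) {
  co <- coef(fit)
  cov_names <- co[!startsWith(names(co), "SCAN")]
  bad <- names(cov_names)[is.na(cov_names)]
  if (length(bad)) {
    abort(paste("covariate term(s) collinear with the design:",
                paste(bad, collapse = ", ")))
  }
}

#' Fit the 3M_BANTOR mixed model
#'
#' The multitask/multisession brain network regression mixed model:
#' distances regressed on per-task covariate-difference blocks and fixed
#' scan-level effects, with one random intercept per (dyad, task) —
#' `b ~ N(0, g_b)`, a separate variance `g_b` per task by default — and
#' homoscedastic residual error. Estimation is restricted maximum
#' likelihood with the fixed effects and residual variance profiled out
#' of sparse normal equations (the random-effect blocks partition the
#' rows, so each REML evaluation is a sparse rank update plus one dense
#' Cholesky); the variance ratios are optimized by bounded quasi-Newton
#' on the log scale (relative tolerance 1e-8, at most 500 iterations),
#' so a zero dyad variance is reached smoothly as a boundary.
#' Fixed-effect degrees of freedom use Satterthwaite's method:
#' `df = 2 (l'Cl)^2 / (d'Vd)` with `C` the fixed-effect covariance at
#' the REML optimum, `d` the (analytic) gradient of `l'C(theta)l` in the
#' variance parameters and `V` twice the inverse of the analytic
#' observed-information Hessian, followed by an analytic Newton polish
#' of the variance ratios so the optimum is resolved to near machine
#' precision.
#'
#' With one task and one repetition per subject every dyad contributes a
#' single row, the random effects are unidentifiable, and the model
#' degenerates to the scan-level-effects F test; in that case the
#' equivalent [fit_f_test_sle()] fit is returned (flagged `degenerate`).
#'
#' @inheritParams fit_f_test
#' @param task_varcomp Separate random-intercept variance per task
#'   (default `TRUE`); `FALSE` pools a single variance across tasks.
#' @param scan_effects Include fixed scan-level effects (default `TRUE`).
#' @param start Optional starting values for the variance ratios
#'   `g_b / sigma^2` (one per task, recycled), e.g. to warm-start
#'   repeated fits.
#' @return A `bantor_fit` object. `tidy()` extracts the fixed-effect
#'   table (Satterthwaite df and p-values); `tidy(effects = "ran_pars")`
#'   the variance components; `glance()` the fit summary.
#' @export
fit_bantor <- function(design, task_varcomp = TRUE, scan_effects = TRUE,
                       start = NULL) {
  if (!inherits(design, "bantor_design")) {
    abort("`design` must come from build_design()")
  }
  terms <- attr(design, "terms")
  intercept <- attr(design, "intercept")
  grp_chr <- paste(design$dyad, design$task)
  grp <- factor(grp_chr)
  if (max(tabulate(as.integer(grp))) < 2) {
    base <- if (scan_effects) fit_f_test_sle(design) else fit_f_test(design)
    base$method <- "bantor"
    base$degenerate <- TRUE
    base$note <- "single scan per subject and task: random effects dropped"
    return(base)
  }
  bx <- build_sparse_X(design, terms, intercept, scan_effects = scan_effects)
  task_of_group <- if (task_varcomp) {
    factor(design$task[match(levels(grp), grp_chr)], levels = bx$task_levels)
  } else {
    factor(rep(1, nlevels(grp)))
  }
  pre <- reml_prepare(bx$X, grp, task_of_group)
  keep <- reml_keep_columns(pre)
  sel <- which(!startsWith(pre$colnames[keep], "SCAN"))
  if (!is.null(start)) start <- rep_len(start, pre$n_tasks)
  sol <- reml_solve(pre, design$distance, keep = keep, start = start,
                    satterthwaite = TRUE, sel = sel)
  kept_names <- pre$colnames[keep]
  table <- tibble(name = kept_names[sel],
                  estimate = unname(sol$beta[sel]),
                  std.error = unname(sol$se[sel]),
                  df = sol$df,
                  statistic = sol$statistic,
                  p.value = sol$p.value)
  scan_sel <- which(startsWith(kept_names, "SCAN"))
  scans <- tibble(scan = sub("^SCAN", "", kept_names[scan_sel]),
                  estimate = unname(sol$beta[scan_sel]),
                  std.error = unname(sol$se[scan_sel]))
  vtasks <- if (task_varcomp) bx$task_levels else "(pooled)"
  varcomp <- bind_rows(tibble(task = vtasks, g = sol$g),
                       tibble(task = "(residual)", g = sol$sigma2))
  note <- if (sol$boundary) "variance component at zero boundary"
  if (sol$boundary) {
    warn("a dyad variance component is estimated at the zero boundary")
  }
  pf <- list(terms = terms, task_levels = bx$task_levels,
             intercept = intercept, scan_levels = bx$scan_levels)
  new_bantor_fit("bantor", NULL, pf, note = note, varcomp = varcomp,
                 table = table, scan_effects = scans,
                 reml = list(nobs = pre$n, rank = sol$rank,
                             grad_norm = sol$grad_norm,
                             vcov_theta = sol$vcov_theta,
                             sigma2 = sol$sigma2, logLik = sol$logLik,
                             objective = sol$objective,
                             iterations = sol$iterations,
                             converged = sol$converged,
                             boundary = sol$boundary,
                             gamma = sol$gamma))
}

# ---- tidy / glance ----------------------------------------------------------

# Map a coefficient name to (task, term). Intercepts are reported with
# term "(Intercept)"; interaction coefficients "task<lvl>:<cov>" map to
# their covariate name.
parse_coef_names <- function(cn, task_levels, terms) {
  task <- rep(NA_character_, length(cn))
  term <- cn
  for (lv in task_levels) {
    ip <- cn == paste0("task", lv)
    task[ip] <- lv
    term[ip] <- "(Intercept)"
    for (tm in terms) {
      im <- cn %in% c(paste0("task", lv, ":", tm), paste0(tm, ":task", lv))
      task[im] <- lv
      term[im] <- tm
    }
  }
  list(task = task, term = term)
}

#' Tidy a bantor model fit
#'
#' @param x A `bantor_fit` from [fit_f_test()], [fit_f_test_sle()] or
#'   [fit_bantor()].
#' @param effects `"fixed"` (default) for the per-task fixed-effect
#'   table; `"ran_pars"` for variance components (mixed fits only);
#'   `"scan"` for the estimated scan-level effects.
#' @param ... Unused.
#' @return A tibble. For `effects = "fixed"`: columns `task`, `term`,
#'   `estimate`, `std.error`, `df`, `statistic`, `p.value` (Satterthwaite
#'   df for mixed fits, residual df otherwise).
#' @export
tidy.bantor_fit <- function(x, effects = c("fixed", "ran_pars", "scan"), ...) {
  effects <- match.arg(effects)
  if (effects == "ran_pars") {
    if (is.null(x$varcomp)) {
      return(tibble(task = character(), g = numeric()))
    }
    return(x$varcomp)
  }
  if (!is.null(x$table)) {
    if (effects == "scan") return(x$scan_effects)
    ct <- x$table
    pc <- parse_coef_names(ct$name, x$task_levels, x$terms)
    return(tibble(task = pc$task, term = pc$term, estimate = ct$estimate,
                  std.error = ct$std.error, df = ct$df,
                  statistic = ct$statistic, p.value = ct$p.value))
  }
  sm <- summary(x$fit)$coefficients
  ct <- data.frame(estimate = sm[, 1], std.error = sm[, 2],
                   df = x$fit$df.residual, statistic = sm[, 3],
                   p.value = sm[, 4],
                   row.names = rownames(sm))
  ct$name <- rownames(ct)
  is_scan <- startsWith(ct$name, "SCAN")
  if (effects == "scan") {
    sc <- ct[is_scan, ]
    return(tibble(scan = sub("^SCAN", "", sc$name), estimate = sc$estimate,
                  std.error = sc$std.error))
  }
  ct <- ct[!is_scan, ]
  pc <- parse_coef_names(ct$name, x$task_levels, x$terms)
  tibble(task = pc$task, term = pc$term, estimate = ct$estimate,
         std.error = ct$std.error, df = ct$df, statistic = ct$statistic,
         p.value = ct$p.value)
}

#' Fit summary for a bantor model
#'
#' @param x A `bantor_fit`.
#' @param ... Unused.
#' @return One-row tibble: method, number of rows, residual sigma, REML
#'   or OLS log-likelihood, convergence flag and any note.
#' @export
glance.bantor_fit <- function(x, ...) {
  if (!is.null(x$reml)) {
    return(tibble(method = x$method, nobs = x$reml$nobs,
                  sigma = sqrt(x$reml$sigma2), logLik = x$reml$logLik,
                  REML = TRUE, degenerate = x$degenerate,
                  converged = x$reml$converged,
                  note = x$note %||% NA_character_))
  }
  tibble(method = x$method,
         nobs = length(stats::fitted(x$fit)),
         sigma = sigma(x$fit),
         logLik = as.numeric(logLik(x$fit)),
         REML = FALSE,
         degenerate = x$degenerate,
         converged = TRUE,
         note = x$note %||% NA_character_)
}

#' @export
#' @method print bantor_fit
print.bantor_fit <- function(x, ...) {
  cat(sprintf("<bantor_fit: %s%s>\n", x$method,
              if (x$degenerate) " (degenerate)" else ""))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  print(tidy(x), n = 20)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
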