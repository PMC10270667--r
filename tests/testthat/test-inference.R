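# A hand-assembled design with disjoint dyads (each subject appears in
# exactly one pair), used to generate responses directly from the mixed
# model.
manual_design <- function(n_dyads, n_reps, task_levels = "T1", seed = 1) {
  set.seed(seed)
  rows <- list()
  for (b in task_levels) {
    for (g in seq_len(n_dyads)) {
      s1 <- sprintf("S%03d", 2 * g - 1)
      s2 <- sprintf("S%03d", 2 * g)
      combo <- expand.grid(rep1 = seq_len(n_reps), rep2 = seq_len(n_reps))
      rows[[length(rows) + 1]] <- tibble::tibble(
        task = b, subject1 = s1, rep1 = combo$rep1,
        subject2 = s2, rep2 = combo$rep2,
        scan1 = paste(s1, b, combo$rep1, sep = "."),
        scan2 = paste(s2, b, combo$rep2, sep = "."),
        dyad = paste(s1, s2, sep = ":"),
        distance = 0, degenerate = FALSE)
    }
  }
  des <- dplyr::bind_rows(rows)
  des$GRP <- as.numeric(match(des$dyad, unique(des$dyad)) %% 2)
  structure(des, class = c("bantor_design", class(tibble::tibble())),
            terms = "GRP", term_types = c(GRP = "continuous"),
            intercept = "task", n_subjects = 2 * n_dyads,
            n_tasks = length(task_levels))
}

test_that("the F test recovers an exact linear relationship", {
  des <- toy_design(6, 1, 2, seed = 30)
  des$distance <- 2 * des$IQ + 1
  fit <- fit_f_test(des)
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$estimate[td$term == "IQ"], 2, tolerance = 1e-8)
  expect_equal(td$estimate[td$term == "(Intercept)"], 1, tolerance = 1e-8)
  expect_lt(glance(fit)$sigma, 1e-8)
})

test_that("F-test p-values are uniform under independent noise", {
  des <- toy_design(8, 1, 1, seed = 31)
  set.seed(32)
  pvals <- replicate(2000, {
    des$distance <- rnorm(nrow(des))
    td <- tidy(fit_f_test(des))
    td$p.value[td$term == "IQ"]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("aggregated F test is block-separable across tasks", {
  des <- toy_design(6, 2, 2, seed = 33)
  set.seed(34)
  des$distance <- des$distance + rnorm(nrow(des), 0, 0.1)
  full <- tidy(fit_f_test(des))
  sub <- des[des$task == "T1", ]
  attrs <- attributes(des)
  for (a in c("terms", "term_types", "intercept", "metric")) {
    attr(sub, a) <- attrs[[a]]
  }
  class(sub) <- class(des)
  alone <- tidy(fit_f_test(sub))
  merged <- merge(full[full$task == "T1", c("term", "estimate")],
                  alone[, c("term", "estimate")], by = "term")
  expect_equal(merged$estimate.x, merged$estimate.y, tolerance = 1e-10)
})

test_that("scan-level fixed effects absorb per-scan distance shifts", {
  des <- toy_design(5, 1, 2, seed = 35)
  set.seed(36)
  des$distance <- des$distance + rnorm(nrow(des), 0, 0.05)
  base <- tidy(fit_f_test_sle(des))
  shifted <- des
  target <- des$scan1[1]
  bump <- 0.7
  hit <- shifted$scan1 == target | shifted$scan2 == target
  shifted$distance[hit] <- shifted$distance[hit] + bump
  after <- tidy(fit_f_test_sle(shifted))
  expect_equal(base$estimate, after$estimate, tolerance = 1e-8)
  sc_base <- tidy(fit_f_test_sle(des), effects = "scan")
  sc_after <- tidy(fit_f_test_sle(shifted), effects = "scan")
  d_alpha <- sc_after$estimate - sc_base$estimate
  names(d_alpha) <- sc_after$scan
  expect_equal(unname(d_alpha[target]), bump, tolerance = 1e-8)
  expect_true(all(abs(d_alpha[names(d_alpha) != target]) < 1e-8))
})

test_that("a covariate collinear with the design is reported by name", {
  des <- toy_design(5, 1, 2, seed = 37)
  des$AGE <- 0 # zero difference everywhere: aliased with anything
  expect_error(fit_f_test_sle(des), "collinear.*AGE")
})

test_that("degenerate single-scan single-task input reproduces the SLE fit", {
  des <- toy_design(8, 1, 1, seed = 38)
  set.seed(39)
  des$distance <- des$distance + rnorm(nrow(des), 0, 0.1)
  fb <- fit_bantor(des)
  fs <- fit_f_test_sle(des)
  expect_true(fb$degenerate)
  expect_equal(fb$method, "bantor")
  expect_tidy_equal(tidy(fb), tidy(fs))
})

test_that("REML fit matches lme4/lmerTest on a small crossed design", {
  skip_if_not_installed("lme4")
  skip_if_not_installed("lmerTest")
  des <- toy_design(8, 2, 2, seed = 40)
  set.seed(41)
  # add dyad effects and noise so variance components are interior
  dyads <- unique(paste(des$dyad, des$task))
  b <- rnorm(length(dyads), 0, 0.2)
  des$distance <- des$distance + b[match(paste(des$dyad, des$task), dyads)] +
    rnorm(nrow(des), 0, 0.1)
  fb <- fit_bantor(des)

  pf <- bantor:::prepare_fit(des, scan_effects = TRUE)
  for (lv in seq_along(pf$task_levels)) {
    pf$df[[paste0(".tk_", lv)]] <-
      as.numeric(pf$df$task == pf$task_levels[lv])
  }
  re <- paste(sprintf("(0 + .tk_%d | dyad)", seq_along(pf$task_levels)),
              collapse = " + ")
  form <- as.formula(paste("distance ~", pf$rhs, "+", re))
  fitT <- suppressMessages(lmerTest::lmer(
    form, data = pf$df, REML = TRUE,
    control = lme4::lmerControl(check.rankX = "silent.drop.cols")))
  sm <- summary(fitT)$coefficients
  sm <- sm[!startsWith(rownames(sm), "SCAN"), ]
  td <- tidy(fb)
  ord <- match(rownames(sm),
               paste0("task", td$task,
                      ifelse(td$term == "(Intercept)", "",
                             paste0(":", td$term))))
  td <- td[ord, ]
  expect_equal(td$estimate, unname(sm[, "Estimate"]), tolerance = 1e-5)
  expect_equal(td$std.error, unname(sm[, "Std. Error"]), tolerance = 1e-4)
  expect_equal(td$df, unname(sm[, "df"]), tolerance = 0.02)
  expect_equal(td$p.value, unname(sm[, "Pr(>|t|)"]), tolerance = 1e-3)

  vc <- as.data.frame(lme4::VarCorr(fitT))
  g_lmer <- vc$vcov[match(paste0(".tk_", seq_along(pf$task_levels)),
                          vc$var1)]
  my_vc <- tidy(fb, "ran_pars")
  expect_equal(my_vc$g[seq_along(g_lmer)], g_lmer, tolerance = 1e-3)
  expect_equal(my_vc$g[my_vc$task == "(residual)"],
               vc$vcov[vc$grp == "Residual"], tolerance = 1e-4)
  expect_equal(glance(fb)$logLik, as.numeric(logLik(fitT)),
               tolerance = 1e-6)
})

test_that("Satterthwaite df equals the classical between-dyad df in a balanced toy", {
  des <- manual_design(12, 2, seed = 42)
  set.seed(43)
  grp_id <- match(des$dyad, unique(des$dyad))
  b <- rnorm(12, 0, 0.5)
  des$distance <- 1 + 0.8 * des$GRP + b[grp_id] + rnorm(nrow(des), 0, 0.3)
  fb <- fit_bantor(des, scan_effects = FALSE)
  td <- tidy(fb)
  expect_equal(td$df[td$term == "GRP"], 12 - 2, tolerance = 1e-6)
})

test_that("REML optimum is a local minimum of the restricted likelihood", {
  des <- manual_design(10, 2, seed = 44)
  set.seed(45)
  grp_id <- match(des$dyad, unique(des$dyad))
  des$distance <- 0.5 * des$GRP + rnorm(10, 0, 0.4)[grp_id] +
    rnorm(nrow(des), 0, 0.2)
  fb <- fit_bantor(des, scan_effects = FALSE)
  gam <- fb$reml$gamma
  bx <- bantor:::build_sparse_X(des, "GRP", "task", scan_effects = FALSE)
  grp <- factor(paste(des$dyad, des$task))
  pre <- bantor:::reml_prepare(bx$X, grp, factor(rep(1, nlevels(grp))))
  keep <- bantor:::reml_keep_columns(pre)
  ys <- bantor:::reml_y_stats(pre, des$distance)
  f <- function(g) bantor:::reml_neg2ll(
    bantor:::reml_eval(pre, ys, g, keep), pre$n)
  f0 <- f(gam)
  expect_lte(f0, f(gam * 1.05) + 1e-7)
  expect_lte(f0, f(gam * 0.95) + 1e-7)
  expect_equal(-2 * fb$reml$logLik, f0, tolerance = 1e-10)
  expect_lt(fb$reml$grad_norm, 1e-8 * nrow(des))
})

test_that("estimates are invariant to subject relabeling and row order", {
  scans <- toy_scans(6, 2, 2, 8, seed = 46)
  cov <- toy_covariates(6, seed = 47)
  d <- network_distances(scans, "euclidean")
  des <- build_design(d, cov)
  set.seed(47)
  des$distance <- des$distance + rnorm(nrow(des), 0, 0.1)

  # consistent relabeling of subjects leaves covariate inference intact
  relab <- setNames(sprintf("Z%02d", sample(6)), sprintf("S%02d", 1:6))
  d2 <- d
  d2$subject1 <- unname(relab[d$subject1])
  d2$subject2 <- unname(relab[d$subject2])
  attr(d2, "metric") <- attr(d, "metric")
  cov2 <- cov
  cov2$subject <- unname(relab[cov$subject])
  des2 <- build_design(d2, cov2)
  key1 <- paste(pmin(relab[des$subject1], relab[des$subject2]),
                pmax(relab[des$subject1], relab[des$subject2]),
                des$task, des$rep1, des$rep2)
  key2 <- paste(pmin(des2$subject1, des2$subject2),
                pmax(des2$subject1, des2$subject2),
                des2$task, des2$rep1, des2$rep2)
  des2$distance <- des$distance[match(key2, key1)]
  # intercepts are identified only up to which redundant scan column is
  # dropped (label-order dependent); covariate inference is invariant
  t_orig <- dplyr::filter(tidy(fit_bantor(des)), term != "(Intercept)")
  t_rel <- dplyr::filter(tidy(fit_bantor(des2)), term != "(Intercept)")
  expect_equal(t_orig$estimate, t_rel$estimate, tolerance = 1e-7)
  expect_equal(t_orig$p.value, t_rel$p.value, tolerance = 1e-5)

  shuffled <- des[sample(nrow(des)), ]
  for (a in c("terms", "term_types", "intercept", "metric")) {
    attr(shuffled, a) <- attr(des, a)
  }
  class(shuffled) <- class(des)
  expect_tidy_equal(tidy(fit_f_test(des)), tidy(fit_f_test(shuffled)))
  tb1 <- tidy(fit_bantor(des))
  tb2 <- tidy(fit_bantor(shuffled))
  expect_equal(tb1$estimate, tb2$estimate, tolerance = 1e-7)
  expect_equal(tb1$p.value, tb2$p.value, tolerance = 1e-5)
})

test_that("mixed-model p-values are calibrated on null model data", {
  des <- manual_design(20, 2, task_levels = c("T1", "T2"), seed = 48)
  bx <- bantor:::build_sparse_X(des, "GRP", "task", scan_effects = FALSE)
  grp_chr <- paste(des$dyad, des$task)
  grp <- factor(grp_chr)
  tog <- factor(des$task[match(levels(grp), grp_chr)])
  pre <- bantor:::reml_prepare(bx$X, grp, tog)
  keep <- bantor:::reml_keep_columns(pre)
  sel <- which(!startsWith(pre$colnames[keep], "SCAN"))
  grp_id <- as.integer(grp)
  set.seed(49)
  rej <- replicate(200, {
    y <- rnorm(nlevels(grp), 0, 0.3)[grp_id] + rnorm(nrow(des), 0, 0.2)
    sol <- bantor:::reml_solve(pre, y, keep = keep, sel = sel)
    nm <- pre$colnames[keep][sel]
    mean(sol$p.value[grepl("GRP", nm)] < 0.05)
  })
  # 200 replicates x 2 tasks: binomial 95% band around 0.05
  expect_gt(mean(rej), 0.05 - 1.96 * sqrt(0.05 * 0.95 / 400))
  expect_lt(mean(rej), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 400))
})

test_that("analytic observed information matches finite differences", {
  des <- manual_design(10, 2, task_levels = c("T1", "T2"), seed = 52)
  set.seed(53)
  grp_chr <- paste(des$dyad, des$task)
  grp <- factor(grp_chr)
  grp_id <- as.integer(grp)
  des$distance <- 0.4 * des$GRP + rnorm(nlevels(grp), 0, 0.4)[grp_id] +
    rnorm(nrow(des), 0, 0.25)
  bx <- bantor:::build_sparse_X(des, "GRP", "task", scan_effects = FALSE)
  tog <- factor(des$task[match(levels(grp), grp_chr)],
                levels = bx$task_levels)
  pre <- bantor:::reml_prepare(bx$X, grp, tog)
  keep <- bantor:::reml_keep_columns(pre)
  ys <- bantor:::reml_y_stats(pre, des$distance)
  opt <- bantor:::reml_optimize(pre, ys, keep)
  ev <- bantor:::reml_eval(pre, ys, pmax(opt$gamma, 0.01), keep)
  e_g <- bantor:::reml_group_resid(pre, ys, ev)
  H_an <- bantor:::reml_information(pre, ev, e_g)
  theta <- c(ev$gamma, ev$sigma2)
  B <- pre$n_tasks
  f <- function(th) {
    e2 <- bantor:::reml_eval(pre, ys, pmax(th[seq_len(B)], 0), keep)
    bantor:::reml_neg2ll(e2, pre$n, sigma2 = th[B + 1])
  }
  H_fd <- bantor:::fd_hessian(f, theta, 1e-4 * (1 + abs(theta)))
  expect_equal(H_an, H_fd, tolerance = 1e-4)
})
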