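# ---- factorial simulation study harness ------------------------------------

#' Run the factorial type-I error / power study
#'
#' For every (signal level, replicate) cell: simulate a dataset, compute
#' each requested metric's pairwise distances, build the regression
#' design and record, for each estimation method, whether each
#' covariate's p-value falls below `alpha` — per task and covariate.
#' Results aggregate to empirical rejection rates (type-I error for the
#' null covariates AGE and SEX, power for IQ and TRT) with binomial
#' Monte-Carlo standard errors.
#'
#' The full-scale design (100 subjects, 268 nodes, 2500 replicates) is a
#' cluster-scale computation; the defaults here are deliberately small so
#' a study runs on a desk machine, and every dimension can be raised back
#' to full scale through the arguments.
#'
#' @param n_replicates Replicates per signal level.
#' @param signal_grid Signal fractions in \[0, 1\] (default 0 to 1 by 0.1).
#' @param metrics Metrics to evaluate; any of `"euclidean"`, `"pcd"`,
#'   `"ks"`, `"jaccard"`, `"lerm"`.
#' @param jaccard_thresholds Top-fraction thresholds used when
#'   `"jaccard"` is requested (default `c(0.2, 0.005)`, i.e. top 20% and
#'   top 0.5%).
#' @param methods Any of `"f_test"`, `"f_test_sle"`, `"bantor"`,
#'   `"mdmr"`.
#' @param terms Covariate columns to test (default
#'   `c("AGE", "SEX", "TRT", "IQ")`).
#' @param alpha Nominal level (default 0.05).
#' @param n_subjects,n_nodes,n_tasks,n_reps,n_time,region_size Simulator
#'   dimensions passed to [simulate_dataset()].
#' @param mdmr_perm Permutations for the MDMR baseline (default 500).
#' @param seed Master seed; per-cell seeds are derived from (seed,
#'   signal index, replicate) so any cell is re-runnable in isolation.
#' @return A `bantor_study` object: `rates` (tidy rejection-rate table
#'   with `signal`, `metric`, `method`, `task`, `term`, `rate`, `n`,
#'   `mc_se`), `raw` (per-replicate p-values), `failures`, `config`.
#' @export
run_study <- function(n_replicates,
                      signal_grid = seq(0, 1, by = 0.1),
                      metrics = c("euclidean", "pcd"),
                      jaccard_thresholds = c(0.2, 0.005),
                      methods = c("f_test", "bantor"),
                      terms = c("AGE", "SEX", "TRT", "IQ"),
                      alpha = 0.05,
                      n_subjects = 30, n_nodes = 60, n_tasks = 3,
                      n_reps = 4, n_time = 300, region_size = 15,
                      mdmr_perm = 500,
                      seed = 1) {
  metrics <- match.arg(metrics, c("euclidean", "pcd", "ks", "jaccard", "lerm"),
                       several.ok = TRUE)
  methods <- match.arg(methods, c("f_test", "f_test_sle", "bantor", "mdmr"),
                       several.ok = TRUE)
  metric_specs <- metric_spec_list(metrics, jaccard_thresholds)
  need_within <- "mdmr" %in% methods

  raw <- list()
  failures <- list()
  for (si in seq_along(signal_grid)) {
    s <- signal_grid[si]
    for (r in seq_len(n_replicates)) {
      cell_seed <- derive_seed(seed, si, r)
      res <- tryCatch(
        study_cell(s, cell_seed, metric_specs, methods, terms,
                   n_subjects, n_nodes, n_tasks, n_reps, n_time,
                   region_size, need_within, mdmr_perm),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          tibble(signal = s, replicate = r, message = conditionMessage(res))
      } else {
        raw[[length(raw) + 1]] <- mutate(res, signal = s, replicate = r)
      }
    }
  }
  failures <- bind_rows(failures)
  n_cells <- length(signal_grid) * n_replicates
  if (nrow(failures) > 0.05 * n_cells) {
    abort(sprintf("more than 5%% of replicates failed (%d of %d); e.g.: %s",
                  nrow(failures), n_cells, failures$message[1]))
  }
  raw <- bind_rows(raw)
  rates <- raw %>%
    filter(.data$term != "(Intercept)") %>%
    group_by(.data$signal, .data$metric, .data$method, .data$task,
             .data$term) %>%
    summarise(rate = mean(.data$p.value < .env$alpha),
              n = dplyr::n(), .groups = "drop") %>%
    mutate(mc_se = sqrt(.data$rate * (1 - .data$rate) / .data$n))
  structure(list(rates = rates, raw = raw, failures = failures,
                 config = list(n_replicates = n_replicates,
                               signal_grid = signal_grid,
                               metrics = metrics,
                               jaccard_thresholds = jaccard_thresholds,
                               methods = methods, terms = terms,
                               alpha = alpha, n_subjects = n_subjects,
                               n_nodes = n_nodes, n_tasks = n_tasks,
                               n_reps = n_reps, n_time = n_time,
                               region_size = region_size, seed = seed)),
            class = "bantor_study")
}

metric_spec_list <- function(metrics, jaccard_thresholds) {
  specs <- list()
  for (m in metrics) {
    if (m == "jaccard") {
      for (th in jaccard_thresholds) {
        specs[[length(specs) + 1]] <-
          list(metric = "jaccard", threshold = th,
               label = sprintf("jaccard_top%g", 100 * th))
      }
    } else {
      specs[[length(specs) + 1]] <- list(metric = m, threshold = NA,
                                         label = m)
    }
  }
  specs
}

# One (signal, replicate) cell: returns tibble(metric, method, task,
# term, p.value).
study_cell <- function(s, cell_seed, metric_specs, methods, terms,
                       n_subjects, n_nodes, n_tasks, n_reps, n_time,
                       region_size, need_within, mdmr_perm) {
  ds <- simulate_dataset(n_subjects = n_subjects, n_nodes = n_nodes,
                         n_tasks = n_tasks, n_reps = n_reps,
                         n_time = n_time, signal = s,
                         region_size = region_size, seed = cell_seed)
  out <- list()
  for (spec in metric_specs) {
    d_all <- network_distances(ds$scans, metric = spec$metric,
                               threshold = if (is.na(spec$threshold)) 0.2
                                           else spec$threshold,
                               include_within = need_within)
    d_btw <- d_all[d_all$subject1 != d_all$subject2, ]
    attr(d_btw, "metric") <- attr(d_all, "metric")
    design <- build_design(d_btw, ds$covariates, terms = terms)
    for (m in setdiff(methods, "mdmr")) {
      fit <- switch(m,
                    f_test = fit_f_test(design),
                    f_test_sle = fit_f_test_sle(design),
                    bantor = fit_bantor(design))
      td <- tidy(fit)
      out[[length(out) + 1]] <-
        mutate(td[td$term %in% terms, c("task", "term", "p.value")],
               metric = spec$label, method = m)
    }
    if ("mdmr" %in% methods) {
      for (tk in unique(ds$scans$task)) {
        dm <- build_distance_matrix(d_all, tk, ds$covariates)
        md <- mdmr_permutation(dm$D, as.data.frame(dm$predictors[terms]),
                               n_perm = mdmr_perm,
                               seed = derive_seed(cell_seed, 5,
                                                  match(tk, unique(ds$scans$task))))
        out[[length(out) + 1]] <-
          tibble(task = tk, term = md$term, p.value = md$p.value,
                 metric = spec$label, method = "mdmr")
      }
    }
  }
  bind_rows(out)
}

#' First signal level reaching a power threshold
#'
#' For each (metric, method, task, covariate) cell, the smallest signal
#' grid value whose rejection rate meets the threshold. Non-monotone
#' power curves that dip back below the threshold after first crossing
#' are flagged.
#'
#' @param study A [run_study()] result.
#' @param threshold Power threshold (default 0.8).
#' @return Tibble: `metric`, `method`, `task`, `term`, `crossing` (first
#'   grid signal fraction with rate >= threshold, `NA` if never
#'   reached), `reached`, `dips_after`.
#' @export
power_crossing <- function(study, threshold = 0.8) {
  rates <- study$rates %>% arrange(.data$signal)
  rates %>%
    group_by(.data$metric, .data$method, .data$task, .data$term) %>%
    summarise(
      crossing = if (any(.data$rate >= .env$threshold)) {
        .data$signal[which(.data$rate >= .env$threshold)[1]]
      } else NA_real_,
      reached = any(.data$rate >= .env$threshold),
      dips_after = {
        hit <- which(.data$rate >= .env$threshold)
        length(hit) > 0 && any(.data$rate[seq_along(.data$rate) > hit[1]] <
                                 .env$threshold)
      },
      .groups = "drop"
    )
}

#' Plot study rejection-rate curves
#'
#' Rejection rate against signal fraction, one panel per (task,
#' covariate), colored by method and grouped by metric, with reference
#' lines at the nominal level and at 80% power.
#'
#' @param object A `bantor_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bantor_study <- function(object, ...) {
  rates <- object$rates
  ggplot2::ggplot(rates,
                  ggplot2::aes(x = .data$signal, y = .data$rate,
                               colour = .data$method,
                               linetype = .data$metric)) +
    ggplot2::geom_hline(yintercept = object$config$alpha,
                        colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0.8, colour = "grey40",
                        linewidth = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$term),
                        cols = ggplot2::vars(.data$task)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "signal fraction", y = "rejection rate")
}

#' @export
#' @method print bantor_study
print.bantor_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<bantor_study: %d replicates x %d signal levels, %d metrics, methods: %s>\n",
              cfg$n_replicates, length(cfg$signal_grid),
              length(metric_spec_list(cfg$metrics, cfg$jaccard_thresholds)),
              paste(cfg$methods, collapse = ", ")))
  print(x$rates, n = 20)
  invisible(x)
}
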