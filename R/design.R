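# ---- pairwise regression design ---------------------------------------------

#' Build the pairwise distance regression design
#'
#' Turns a long table of same-task, distinct-subject scan-pair distances
#' and a subject covariate table into the regression design: one row per
#' (subject pair, task, repetition combination), with covariate-difference
#' regressors — `|x_a - x_d|` for continuous covariates and the indicator
#' `1{x_a != x_d}` for categorical ones — plus dyad and scan identifiers
#' used by the fitting functions.
#'
#' @param distances Output of [network_distances()] (a single metric).
#'   Same-subject rows, if present, are dropped with a message.
#' @param covariates Tibble with one row per subject: a `subject` column
#'   plus covariate columns. Numeric columns are treated as continuous,
#'   everything else as categorical.
#' @param terms Character vector of covariate column names to build
#'   regressors for; defaults to every column except `subject`.
#' @param intercept `"task"` (default) for per-task intercepts, `"global"`
#'   for a single intercept, `"none"`.
#' @return A `bantor_design` tibble with columns `task`, `subject1`,
#'   `rep1`, `subject2`, `rep2`, `scan1`, `scan2`, `dyad`, `distance`,
#'   and one regressor column per term. Metadata (metric, terms, term
#'   types, intercept rule, counts) is stored in attributes.
#' @export
build_design <- function(distances, covariates, terms = NULL,
                         intercept = c("task", "global", "none")) {
  intercept <- match.arg(intercept)
  distances <- as_tibble(distances)
  covariates <- as_tibble(covariates)
  if (length(unique(distances$metric)) > 1) {
    abort("`distances` mixes metrics; build one design per metric")
  }
  if (!"subject" %in% names(covariates)) {
    abort("`covariates` must have a `subject` column")
  }
  if (anyDuplicated(covariates$subject)) abort("duplicate subject ids")
  if (is.null(terms)) terms <- setdiff(names(covariates), "subject")
  missing_cov <- setdiff(terms, names(covariates))
  if (length(missing_cov)) {
    abort(paste("covariates missing columns:", paste(missing_cov, collapse = ", ")))
  }
  if (anyNA(covariates[terms])) abort("missing values in designated covariates")
  subj <- unique(c(distances$subject1, distances$subject2))
  absent <- setdiff(subj, covariates$subject)
  if (length(absent)) {
    abort(paste("subjects missing from covariate table:",
                paste(head(absent, 5), collapse = ", ")))
  }

  n_within <- sum(distances$subject1 == distances$subject2)
  if (n_within > 0) {
    inform(sprintf("dropping %d same-subject scan pairs", n_within))
    distances <- distances[distances$subject1 != distances$subject2, ]
  }

  des <- distances %>%
    rename(distance = "value") %>%
    mutate(
      scan1 = paste(.data$subject1, .data$task, .data$rep1, sep = "."),
      scan2 = paste(.data$subject2, .data$task, .data$rep2, sep = "."),
      dyad = paste(pmin(.data$subject1, .data$subject2),
                   pmax(.data$subject1, .data$subject2), sep = ":")
    )

  term_types <- vapply(covariates[terms], function(col) {
    if (is.numeric(col)) "continuous" else "categorical"
  }, character(1))
  i1 <- match(des$subject1, covariates$subject)
  i2 <- match(des$subject2, covariates$subject)
  for (tm in terms) {
    col <- covariates[[tm]]
    des[[tm]] <- if (term_types[[tm]] == "continuous") {
      abs(col[i1] - col[i2])
    } else {
      as.numeric(col[i1] != col[i2])
    }
  }

  des <- des %>%
    select(all_of(c("task", "subject1", "rep1", "subject2", "rep2",
                    "scan1", "scan2", "dyad", "distance", "degenerate")),
           all_of(terms)) %>%
    arrange(.data$task, .data$subject1, .data$subject2, .data$rep1, .data$rep2)

  structure(des,
            class = c("bantor_design", class(tibble())),
            metric = attr(distances, "metric"),
            terms = terms,
            term_types = term_types,
            intercept = intercept,
            n_subjects = length(unique(covariates$subject)),
            n_tasks = length(unique(des$task)))
}

#' Assemble a complete per-task distance matrix for MDMR
#'
#' MDMR requires a full scan-by-scan distance matrix, so within-subject
#' distances are included (unlike the regression design). Scans are
#' ordered lexicographically by (subject, repetition).
#'
#' @param distances Output of [network_distances()] with
#'   `include_within = TRUE`.
#' @param task Which task's matrix to assemble.
#' @param covariates Optional subject covariate table; if supplied, a
#'   scan-level predictor table (covariates repeated per repetition) is
#'   attached.
#' @return List with `D` (symmetric matrix, zero diagonal), `scans`
#'   (tibble of subject/rep in matrix order) and, if requested,
#'   `predictors`.
#' @export
build_distance_matrix <- function(distances, task, covariates = NULL) {
  distances <- as_tibble(distances)
  d <- distances[distances$task == task, ]
  if (nrow(d) == 0) abort(sprintf("no distances for task '%s'", task))
  scans <- tibble(
    subject = c(d$subject1, d$subject2),
    rep = c(d$rep1, d$rep2)
  ) %>% distinct() %>% arrange(.data$subject, .data$rep)
  n <- nrow(scans)
  key <- paste(scans$subject, scans$rep, sep = ".")
  i <- match(paste(d$subject1, d$rep1, sep = "."), key)
  j <- match(paste(d$subject2, d$rep2, sep = "."), key)
  D <- matrix(NA_real_, n, n, dimnames = list(key, key))
  diag(D) <- 0
  D[cbind(i, j)] <- d$value
  D[cbind(j, i)] <- d$value
  if (anyNA(D)) {
    miss <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    abort(paste0("incomplete pairings; missing e.g.: ",
                 paste(sprintf("%s~%s", key[miss[, 1]], key[miss[, 2]])[
                   seq_len(min(5, nrow(miss)))], collapse = ", "),
                 " (use include_within = TRUE in network_distances())"))
  }
  out <- list(D = D, scans = scans)
  if (!is.null(covariates)) {
    covariates <- as_tibble(covariates)
    idx <- match(scans$subject, covariates$subject)
    if (anyNA(idx)) abort("subjects missing from covariate table")
    out$predictors <- covariates[idx, , drop = FALSE]
  }
  structure(out, class = "bantor_distmat")
}
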