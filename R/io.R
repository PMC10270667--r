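# ---- plain-text I/O ---------------------------------------------------------

detect_sep <- function(line) {
  if (grepl(",", line)) "," else if (grepl("\t", line)) "\t" else ""
}

#' Read a square connection matrix from a delimited text file
#'
#' Accepts dense CSV/TSV or whitespace-separated matrices. A header row
#' and a leading row-name column are auto-detected (non-numeric first
#' cells) and the node labels retained as dimnames.
#'
#' @param path File path.
#' @return Square numeric matrix, validated with
#'   [validate_connection_matrix()] skipped (call it yourself if the
#'   file is a correlation matrix); dimnames carry any node labels.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  first <- readLines(path, n = 1)
  sep <- detect_sep(first)
  nf <- count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    abort(sprintf("ragged rows: line %d has %d fields, expected %d",
                  bad, nf[bad], nf[1]))
  }
  cells <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
  cells <- cells[cells != ""]
  header <- anyNA(suppressWarnings(as.numeric(gsub("\"", "", cells))))
  df <- read.table(path, sep = sep, header = header,
                   check.names = FALSE, stringsAsFactors = FALSE)
  rownames_col <- anyNA(suppressWarnings(as.numeric(as.character(df[[1]]))))
  if (rownames_col) {
    rn <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  } else {
    rn <- NULL
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) abort("non-numeric cells in matrix file")
  if (nrow(m) != ncol(m)) {
    abort(sprintf("matrix is not square (%d x %d)", nrow(m), ncol(m)))
  }
  if (!is.null(rn)) rownames(m) <- rn
  if (header && is.null(rn)) rownames(m) <- colnames(m)
  m
}

#' Write a square matrix as CSV
#'
#' Inverse of [read_matrix()]: writes with a header row (node labels, or
#' `V1..Vn` if unnamed) and no row-name column, at full double
#' precision.
#'
#' @param x Square numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  write.csv(as.data.frame(x, check.names = FALSE), path, row.names = FALSE)
  invisible(path)
}

#' Read a scan manifest
#'
#' A manifest is a CSV with columns `subject`, `task`, `rep`, `path`
#' pointing at matrix files; this loads every matrix (validated) into a
#' scan table usable by [network_distances()].
#'
#' @param path Manifest CSV path.
#' @param validate Validate each matrix as a connection matrix
#'   (default `TRUE`).
#' @return Scan tibble with a `matrix` list-column.
#' @export
read_manifest <- function(path, validate = TRUE) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject", "task", "rep", "path")
  if (!all(needed %in% names(man))) {
    abort("manifest must have columns subject, task, rep, path")
  }
  if (anyDuplicated(man[c("subject", "task", "rep")])) {
    abort("duplicate (subject, task, rep) rows in manifest")
  }
  base <- dirname(path)
  mats <- lapply(man$path, function(p) {
    fp <- if (file.exists(p)) p else file.path(base, p)
    m <- read_matrix(fp)
    if (validate) m <- validate_connection_matrix(m)
    m
  })
  tibble(subject = as.character(man$subject),
         task = as.character(man$task),
         rep = man$rep, matrix = mats)
}

#' Write a simulated dataset to disk
#'
#' Writes one matrix CSV per scan plus `covariates.csv` and
#' `manifest.csv` into a directory, round-trippable through
#' [read_manifest()].
#'
#' @param sim A `bantor_sim` from [simulate_dataset()] (or any scan
#'   table plus covariates).
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scans <- scan_table(sim)
  files <- sprintf("%s_%s_rep%s.csv", scans$subject, scans$task, scans$rep)
  for (i in seq_len(nrow(scans))) {
    write_matrix(scans$matrix[[i]], file.path(dir, files[i]))
  }
  man <- data.frame(subject = scans$subject, task = scans$task,
                    rep = scans$rep, path = files)
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (inherits(sim, "bantor_sim")) {
    write.csv(as.data.frame(sim$covariates),
              file.path(dir, "covariates.csv"), row.names = FALSE)
  }
  invisible(file.path(dir, "manifest.csv"))
}
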