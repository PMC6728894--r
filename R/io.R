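# TSV dialect used throughout: tab separator, dot decimal, header row,
# doubles written with 17 significant digits so write -> read round-trips
# are lossless.

format_num <- function(x) {
  out <- vapply(x, function(v) format(v, digits = 17, scientific = FALSE,
                                      trim = TRUE), character(1))
  out[is.na(x)] <- "NA"
  out
}

#' Write one subject's ROI time series to TSV
#'
#' @param ts An [roi_timeseries()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(ts$values), collapse = "\t"), con)
  apply(ts$values, 1, function(row)
    writeLines(paste(format_num(row), collapse = "\t"), con))
  invisible(path)
}

#' Read one subject's ROI time series from TSV
#'
#' Strict reader: every row must have the header's width and parse as
#' numeric; violations are reported with their line number.
#'
#' @param path Input TSV (header row of region labels, T numeric rows).
#' @param subject_id Subject id for the result; defaults to the file
#'   name without extension.
#' @param tr_seconds Repetition time to record.
#' @return An [roi_timeseries()].
#' @export
read_timeseries_tsv <- function(path, subject_id = NULL, tr_seconds = 2) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2)
    stop(path, ": no data rows", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  labels <- fields[[1]]
  n <- length(labels)
  rows <- lapply(seq(2, length(lines)), function(l) {
    f <- fields[[l]]
    if (length(f) != n)
      stop(sprintf("%s line %d: expected %d fields, found %d",
                   path, l, n, length(f)), call. = FALSE)
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop(sprintf("%s line %d: non-numeric value", path, l), call. = FALSE)
    v
  })
  values <- do.call(rbind, rows)
  colnames(values) <- labels
  roi_timeseries(values,
                 subject_id = subject_id %||%
                   sub("\\.tsv$", "", basename(path)),
                 tr_seconds = tr_seconds, region_labels = labels)
}

#' Write a cohort to a directory of TSV files
#'
#' One `<subject_id>.tsv` per subject, plus `covariates.tsv` and a
#' `cohort_spec.json` sidecar recording the full generator
#' specification.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ts in cohort$subjects)
    write_timeseries_tsv(ts, file.path(dir, paste0(ts$subject_id, ".tsv")))
  write_covariates_tsv(cohort$covariates, file.path(dir, "covariates.tsv"))
  jsonlite::write_json(unclass(cohort$spec),
                       file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @param covariates Covariates tibble.
#' @param path File path.
#' @export
write_covariates_tsv <- function(covariates, path) {
  df <- as.data.frame(covariates)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], format_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_covariates_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Read a directory of subject time-series TSVs
#'
#' Loads every `*.tsv` except `covariates.tsv`, checks that all subjects
#' share the same region labels in the same order (mismatches name both
#' files), and attaches `covariates.tsv` when present.
#'
#' @param dir Directory path.
#' @param tr_seconds Repetition time recorded on each series.
#' @return A `cohort`-like list with `subjects` and (possibly `NULL`)
#'   `covariates`.
#' @export
read_timeseries_dir <- function(dir, tr_seconds = 2) {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  files <- files[basename(files) != "covariates.tsv"]
  if (length(files) == 0)
    stop("no subject TSV files in ", dir, call. = FALSE)
  subjects <- lapply(files, read_timeseries_tsv, tr_seconds = tr_seconds)
  names(subjects) <- vapply(subjects, function(s) s$subject_id, character(1))
  ref <- colnames(subjects[[1]]$values)
  for (k in seq_along(subjects)[-1]) {
    if (!identical(colnames(subjects[[k]]$values), ref))
      stop(sprintf("region labels differ between %s and %s",
                   files[1], files[k]), call. = FALSE)
  }
  cov_path <- file.path(dir, "covariates.tsv")
  covariates <- if (file.exists(cov_path)) read_covariates_tsv(cov_path)
                else NULL
  structure(list(subjects = subjects, covariates = covariates, spec = NULL),
            class = "cohort")
}

#' Write/read a square labelled matrix as TSV
#'
#' @param m Square numeric matrix with row/column names.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix_tsv <- function(m, path) {
  labels <- rownames(m) %||% sprintf("R%03d", seq_len(nrow(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("region", labels), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(labels[i], format_num(m[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labels
  storage.mode(m) <- "double"
  m
}

#' Load an atlas table
#'
#' Reads a region table with columns `index`, `label`, `lobe`, `x`, `y`,
#' `z` (MNI centroid coordinates in mm). The bundled default,
#' `atlas246_synthetic.tsv`, is a synthetic stand-in with 246 generic
#' labels and synthetic coordinates, intended for visualization-export
#' plumbing and tests rather than anatomical localization.
#'
#' @param path Atlas TSV; default is the bundled synthetic 246-region
#'   table.
#' @return Tibble with the columns above.
#' @export
load_atlas <- function(path = NULL) {
  path <- path %||% system.file("extdata", "atlas246_synthetic.tsv",
                                package = "costnet")
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("index", "label", "lobe", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("atlas must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$label))
    stop("atlas labels must be unique", call. = FALSE)
  if (!identical(as.integer(df$index), seq_len(nrow(df))))
    stop("atlas indices must be contiguous starting at 1", call. = FALSE)
  tibble::as_tibble(df)
}

#' Export BrainNetViewer node and edge files
#'
#' Writes the whitespace-separated `.node` (x, y, z, color group, size,
#' label) and `.edge` (N x N signed t matrix, zero where no finding)
#' files consumed by the BrainNetViewer visualization tool.
#'
#' @param findings Tibble with `region_i`, `region_j`, `t` (e.g.
#'   `tidy()` of an `nbs_result`); may have zero rows.
#' @param nodal_scores Named numeric vector (names = atlas labels) used
#'   for node size; missing regions get size 0.
#' @param atlas Atlas tibble from [load_atlas()].
#' @param node_path,edge_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
export_brainnetviewer <- function(findings, nodal_scores, atlas,
                                  node_path, edge_path) {
  labels <- atlas$label
  n <- length(labels)
  unknown <- setdiff(unique(c(findings$region_i, findings$region_j,
                              names(nodal_scores))), labels)
  if (length(unknown) > 0)
    stop("label(s) not in atlas: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  size <- stats::setNames(rep(0, n), labels)
  if (length(nodal_scores) > 0)
    size[names(nodal_scores)] <- as.numeric(nodal_scores)
  color <- as.integer(factor(atlas$lobe))
  node <- data.frame(x = atlas$x, y = atlas$y, z = atlas$z,
                     color = color, size = format_num(size),
                     label = labels)
  write.table(node, node_path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  edge <- matrix(0, n, n)
  if (nrow(findings) > 0) {
    i <- match(findings$region_i, labels)
    j <- match(findings$region_j, labels)
    edge[cbind(i, j)] <- findings$t
    edge[cbind(j, i)] <- findings$t
  }
  con <- file(edge_path, "w")
  on.exit(close(con))
  for (r in seq_len(n))
    writeLines(paste(format_num(edge[r, ]), collapse = " "), con)
  invisible(list(node = node_path, edge = edge_path))
}
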