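#' Construct a parcellated ROI time-series object
#'
#' The pipeline's raw input: one subject's T x N table of region-mean
#' signals (rows = volumes, columns = regions), with the repetition time
#' carried along so frequency-domain operations know the sampling rate.
#'
#' @param values Numeric T x N matrix; column names are the region labels.
#' @param subject_id Subject identifier string.
#' @param tr_seconds Repetition time (sampling interval) in seconds.
#' @param region_labels Optional character vector of N labels; defaults to
#'   existing column names or `R001 ... RN`.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, subject_id = "sub-001", tr_seconds = 2,
                           region_labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 3)
    stop("a time series needs at least 3 time points", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("time series contains missing or non-finite values", call. = FALSE)
  assert_scalar_number(tr_seconds, "tr_seconds", min = 1e-9)
  labels <- region_labels %||% colnames(values) %||%
    sprintf("R%03d", seq_len(ncol(values)))
  if (length(labels) != ncol(values))
    stop("region_labels length must equal the number of columns", call. = FALSE)
  if (anyDuplicated(labels))
    stop("region labels must be unique", call. = FALSE)
  colnames(values) <- labels
  structure(
    list(subject_id = as.character(subject_id), values = values,
         tr_seconds = tr_seconds),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %s: %d time points x %d regions, TR = %gs\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$values)

#' @rdname roi_timeseries
#' @param x An `roi_timeseries` object.
#' @param ... Unused.
#' @export
region_labels <- function(x, ...) UseMethod("region_labels")

#' @export
region_labels.roi_timeseries <- function(x, ...) colnames(x$values)
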