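#' Fisher z-transform of correlation coefficients
#'
#' `atanh(r)` with `|r|` clamped to `1 - 1e-15` first so that perfectly
#' correlated pairs map to a large finite value rather than infinity; any
#' clamping is reported with a message.
#'
#' @param r Numeric vector or matrix of correlations in `[-1, 1]`.
#' @return Object of the same shape with the transform applied.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  clamp <- 1 - 1e-15
  n_clamped <- sum(abs(r) > clamp, na.rm = TRUE)
  if (n_clamped > 0)
    message(sprintf("fisher_z: clamped %d value(s) with |r| > 1 - 1e-15",
                    n_clamped))
  atanh(pmin(pmax(r, -clamp), clamp))
}

#' Pearson functional-connectivity matrix with Fisher z transform
#'
#' Correlates every pair of region time courses, giving the subject's
#' N x N functional-connectivity matrix `r` and its Fisher z transform
#' `z` (diagonal of `z` is set to 0 and carries no meaning).
#'
#' @param ts An [roi_timeseries()].
#' @return A `connectivity_matrix` object (fields `subject_id`, `r`, `z`).
#' @export
fc_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  sds <- apply(ts$values, 2, sd)
  if (any(sds == 0))
    stop("zero-variance region(s): ",
         paste(colnames(ts$values)[sds == 0], collapse = ", "),
         call. = FALSE)
  r <- cor(ts$values)
  r <- (r + t(r)) / 2  # guard against asymmetric rounding
  z <- suppressMessages(fisher_z(r))
  diag(z) <- 0
  structure(list(subject_id = ts$subject_id, r = r, z = z),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s: %d x %d\n",
              x$subject_id, nrow(x$r), ncol(x$r)))
  invisible(x)
}

#' The default cost grid
#'
#' The 31 network densities 0.10, 0.11, ..., 0.40 used for the threshold
#' sweep.
#'
#' @return Numeric vector of length 31.
#' @export
default_cost_grid <- function() round(seq(0.10, 0.40, by = 0.01), 2)

extract_z <- function(cm) {
  if (inherits(cm, "connectivity_matrix")) cm$z
  else if (is.matrix(cm) && nrow(cm) == ncol(cm)) cm
  else stop("expected a connectivity_matrix or square numeric matrix",
            call. = FALSE)
}

#' Binarize a connectivity matrix at a fixed cost
#'
#' Keeps the `E = round(cost * N * (N - 1) / 2)` edges (round half up)
#' with the largest absolute Fisher-z values, so every subject's network
#' has exactly the same number of edges at a given cost regardless of
#' overall correlation level. Ties at the cut are broken by lexicographic
#' `(i, j)` order and reported with a message.
#'
#' @param cm A `connectivity_matrix` (from [fc_matrix()]) or a square
#'   symmetric z matrix.
#' @param cost Target density in `(0, 1)`.
#' @return A `binary_network`: list with `adjacency` (0/1 integer
#'   matrix), `cost`, `n_edges`, `subject_id`, `n_tied` (edges involved
#'   in a tie at the cut).
#' @export
threshold_at_cost <- function(cm, cost) {
  assert_scalar_number(cost, "cost", min = 1e-12, max = 1 - 1e-12)
  z <- extract_z(cm)
  n <- nrow(z)
  if (any(z != t(z)))
    stop("z matrix must be symmetric", call. = FALSE)
  up <- upper_pairs(n)
  zv <- abs(z[up$idx])
  if (any(!is.finite(zv)))
    stop("non-finite off-diagonal z value(s); refusing to threshold",
         call. = FALSE)
  m <- length(zv)
  e <- round_half_up(cost * m)
  if (e <= 0 || e >= m)
    stop(sprintf("degenerate network: cost %g gives %d of %d edges",
                 cost, e, m), call. = FALSE)
  ord <- order(-zv, up$i, up$j)
  keep <- ord[seq_len(e)]
  cutval <- zv[ord[e]]
  n_tied <- if (zv[ord[e + 1]] == cutval) sum(zv == cutval) else 0L
  if (n_tied > 0)
    message(sprintf(
      "threshold_at_cost: %d tied |z| values at the cut (cost %g); ",
      n_tied, cost), "lexicographic (i, j) tie-break applied")
  a <- matrix(0L, n, n)
  a[up$idx[keep]] <- 1L
  a <- a + t(a)
  dimnames(a) <- dimnames(z)
  structure(list(adjacency = a, cost = cost, n_edges = as.integer(e),
                 subject_id = if (inherits(cm, "connectivity_matrix"))
                   cm$subject_id else NA_character_,
                 n_tied = as.integer(n_tied)),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %s: %d nodes, %d edges (cost %.3g)\n",
              x$subject_id %||% "?", nrow(x$adjacency), x$n_edges, x$cost))
  invisible(x)
}

#' Threshold a connectivity matrix across a cost grid
#'
#' @param cm A `connectivity_matrix` or z matrix.
#' @param costs Strictly increasing grid in `(0, 1)`; defaults to
#'   [default_cost_grid()].
#' @return A `network_sweep`: list with `subject_id`, `costs`, and
#'   `networks` (one `binary_network` per cost). Because thresholding is
#'   by |z| rank, the edge sets are nested along the grid.
#' @export
sweep_costs <- function(cm, costs = default_cost_grid()) {
  if (length(costs) < 1 || any(diff(costs) <= 0))
    stop("costs must be strictly increasing", call. = FALSE)
  nets <- lapply(costs, function(k) threshold_at_cost(cm, k))
  structure(list(
    subject_id = if (inherits(cm, "connectivity_matrix"))
      cm$subject_id else NA_character_,
    costs = costs, networks = nets),
    class = "network_sweep")
}

#' @export
print.network_sweep <- function(x, ...) {
  cat(sprintf("<network_sweep> %s: %d costs in [%.3g, %.3g]\n",
              x$subject_id %||% "?", length(x$costs),
              min(x$costs), max(x$costs)))
  invisible(x)
}
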