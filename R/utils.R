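# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic counter scheme used to hand independent seeds to
#' subjects, ensemble members and permutation engines so that parallel or
#' reordered execution cannot change results. Stays inside 32-bit integer
#' range.
#'
#' @param master Integer master seed.
#' @param index Non-negative integer counter.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master),
            is.numeric(index), length(index) == 1, index >= 0)
  # Lehmer-style step on the 2^31-1 field; master folded in first.
  m <- 2147483647
  s <- (abs(as.numeric(master)) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + as.numeric(index) * 16807) %% m
  as.integer(if (s == 0) 1 else s)
}

round_half_up <- function(x) floor(x + 0.5)

# Upper-triangle index pairs (i < j) of an n x n matrix, column-major
# order matching which(upper.tri(.)).
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)))
  j <- ((idx - 1) %/% n) + 1
  i <- idx - (j - 1) * n
  list(i = i, j = j, idx = idx)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (x < min || x > max)
    stop(sprintf("`%s` = %g is outside [%g, %g]", name, x, min, max),
         call. = FALSE)
  invisible(x)
}

# Validate a binary adjacency matrix: square, 0/1, symmetric, hollow.
validate_adjacency <- function(a) {
  if (!is.matrix(a) || nrow(a) != ncol(a))
    stop("adjacency must be a square matrix", call. = FALSE)
  if (!all(a %in% c(0L, 1L)))
    stop("adjacency must contain only 0 and 1", call. = FALSE)
  if (any(a != t(a)))
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(a) != 0))
    stop("adjacency must have a zero diagonal (no self-loops)", call. = FALSE)
  invisible(a)
}

as_adjacency <- function(net) {
  if (inherits(net, "binary_network")) net$adjacency
  else {
    storage.mode(net) <- "integer"
    validate_adjacency(net)
    net
  }
}
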