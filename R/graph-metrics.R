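#' Shortest-path length matrix of a binary network
#'
#' Unweighted breadth-first distances between all node pairs; `Inf` marks
#' disconnected pairs.
#'
#' @param net A `binary_network` (or 0/1 adjacency matrix).
#' @return N x N numeric matrix, zero diagonal, symmetric.
#' @export
shortest_path_matrix <- function(net) {
  a <- as_adjacency(net)
  d <- .bfs_distances_cpp(a)
  d[d < 0] <- Inf
  storage.mode(d) <- "double"
  dimnames(d) <- dimnames(a)
  d
}

#' Per-node clustering coefficient
#'
#' For node i with degree `Di` and `Ei` edges among its neighbors, the
#' value is `Ei / (Di * (Di - 1) / 2)`; nodes with `Di < 2` score 0 (and
#' still count in the network mean, so Cp is always an N-term mean).
#'
#' @param net A `binary_network` (or adjacency matrix).
#' @return Named numeric vector of length N; `mean()` of it is Cp.
#' @export
clustering_coefficient <- function(net) {
  a <- as_adjacency(net)
  v <- .clustering_cpp(a)
  names(v) <- rownames(a)
  v
}

#' Characteristic path length with fragmentation report
#'
#' Mean shortest-path length over connected (finite) node pairs. For a
#' fully connected graph this is the usual `1 / (N (N - 1)) * sum Li,j`;
#' disconnected pairs are excluded from the mean and counted instead.
#'
#' @param net A `binary_network` (or adjacency matrix).
#' @return List with `Lp`, `infinite_pairs` (unordered disconnected
#'   pairs), and `fragmented` (logical).
#' @export
characteristic_path_length <- function(net) {
  a <- as_adjacency(net)
  res <- .cp_lp_cpp(a)
  if (!is.finite(res[2]))
    stop("graph has no finite off-diagonal distances", call. = FALSE)
  list(Lp = res[2], infinite_pairs = as.integer(res[3]),
       fragmented = res[3] > 0)
}

#' Global efficiency
#'
#' Mean of inverse shortest-path lengths over all ordered node pairs,
#' with `1 / Inf = 0`, so fragmentation lowers efficiency instead of
#' making it undefined.
#'
#' @param net A `binary_network` (or adjacency matrix).
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  d <- shortest_path_matrix(net)
  inv <- 1 / d
  diag(inv) <- 0
  n <- nrow(d)
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of each node's
#' neighbor-induced subgraph; nodes with fewer than 2 neighbors
#' contribute 0.
#'
#' @param net A `binary_network` (or adjacency matrix).
#' @param per_node If `TRUE`, return the per-node vector instead of the
#'   mean.
#' @return Scalar in `[0, 1]`, or a named vector when `per_node = TRUE`.
#' @export
local_efficiency <- function(net, per_node = FALSE) {
  a <- as_adjacency(net)
  v <- .local_efficiency_cpp(a)
  names(v) <- rownames(a)
  if (per_node) v else mean(v)
}

#' Nodal efficiency
#'
#' For each node, the mean inverse distance to every other node
#' (`1 / Inf = 0`): the information-propagation ability of the node. A
#' node scores 0 exactly when it is isolated.
#'
#' @param net A `binary_network` (or adjacency matrix).
#' @return Named numeric vector of length N; its mean equals
#'   [global_efficiency()].
#' @export
nodal_efficiency <- function(net) {
  d <- shortest_path_matrix(net)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (nrow(d) - 1)
}

#' Global metrics of one binary network
#'
#' @param net A `binary_network`.
#' @return One-row tibble: `cost`, `Cp`, `Lp`, `Eglobal`, `Elocal`,
#'   `infinite_pairs`, `fragmented`.
#' @export
global_metrics <- function(net) {
  a <- as_adjacency(net)
  res <- .cp_lp_cpp(a)
  d <- shortest_path_matrix(a)
  inv <- 1 / d
  diag(inv) <- 0
  n <- nrow(a)
  tibble::tibble(
    cost = if (inherits(net, "binary_network")) net$cost else NA_real_,
    Cp = res[1],
    Lp = res[2],
    Eglobal = sum(inv) / (n * (n - 1)),
    Elocal = mean(.local_efficiency_cpp(a)),
    infinite_pairs = as.integer(res[3]),
    fragmented = res[3] > 0
  )
}

#' Nodal metrics of one binary network
#'
#' @param net A `binary_network`.
#' @return Tibble with one row per region: `region`, `cost`, `degree`,
#'   `clustering`, `Enodal`.
#' @export
nodal_metrics <- function(net) {
  a <- as_adjacency(net)
  labels <- rownames(a) %||% sprintf("R%03d", seq_len(nrow(a)))
  tibble::tibble(
    region = labels,
    cost = if (inherits(net, "binary_network")) net$cost else NA_real_,
    degree = as.integer(rowSums(a)),
    clustering = as.numeric(.clustering_cpp(a)),
    Enodal = as.numeric(nodal_efficiency(a))
  )
}

#' Global metric curves across a cost sweep
#'
#' @param sweep A `network_sweep` from [sweep_costs()].
#' @return Tibble with one row per cost: `subject_id`, `cost`, `Cp`,
#'   `Lp`, `Eglobal`, `Elocal`, `infinite_pairs`, `fragmented`.
#' @export
metric_curves <- function(sweep) {
  stopifnot(inherits(sweep, "network_sweep"))
  out <- purrr::map_dfr(sweep$networks, global_metrics)
  tibble::add_column(out, subject_id = sweep$subject_id, .before = 1)
}

#' Nodal metric curves across a cost sweep
#'
#' @param sweep A `network_sweep`.
#' @return Tibble: `subject_id`, `region`, `cost`, `degree`,
#'   `clustering`, `Enodal`.
#' @export
nodal_curves <- function(sweep) {
  stopifnot(inherits(sweep, "network_sweep"))
  out <- purrr::map_dfr(sweep$networks, nodal_metrics)
  tibble::add_column(out, subject_id = sweep$subject_id, .before = 1)
}
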