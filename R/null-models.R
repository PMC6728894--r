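#' Degree-preserving rewiring of a binary network
#'
#' Randomizes topology with `swap_factor * n_edges` attempted double-edge
#' swaps (Maslov-Sneppen): two edges `(a,b)` and `(c,d)` become `(a,d)`
#' and `(c,b)` unless that would create a self-loop or duplicate edge.
#' The degree of every node is exactly conserved. On saturated graphs
#' (e.g. complete graphs) no valid swap exists and the input is returned
#' unchanged with a message.
#'
#' @param net A `binary_network`.
#' @param swap_factor Attempted swaps per edge (default 10).
#' @param seed Integer seed (R's RNG drives the swap sequence).
#' @return A rewired `binary_network` with the same cost and edge count.
#' @export
rewire_degree_preserving <- function(net, swap_factor = 10, seed = 1L) {
  a <- as_adjacency(net)
  n_edges <- sum(a) / 2
  if (n_edges < 2)
    stop("rewiring needs at least 2 edges", call. = FALSE)
  res <- withr::with_seed(as.integer(seed),
                          .rewire_cpp(a, as.integer(swap_factor * n_edges)))
  if (res$n_swaps == 0)
    message("rewire_degree_preserving: no valid swap found; ",
            "returning the input network")
  out <- res$adjacency
  dimnames(out) <- dimnames(a)
  structure(list(adjacency = out,
                 cost = if (inherits(net, "binary_network")) net$cost
                        else NA_real_,
                 n_edges = as.integer(n_edges),
                 subject_id = if (inherits(net, "binary_network"))
                   net$subject_id else NA_character_,
                 n_tied = 0L),
            class = "binary_network")
}

#' Ensemble of matched random networks
#'
#' Generates `n` independent degree-preserving rewirings of `net` (same
#' node count, edge count and degree sequence) and scores each for the
#' clustering coefficient Cp and characteristic path length Lp. Member
#' seeds are derived from `seed` by a counter scheme, so the ensemble is
#' reproducible and order-independent.
#'
#' @param net A `binary_network`.
#' @param n Ensemble size (default 100).
#' @param seed Integer master seed.
#' @param swap_factor Attempted swaps per edge for each member.
#' @return A `null_ensemble`: list with vectors `Cp_rand`, `Lp_rand`,
#'   means `mean_Cp_rand`, `mean_Lp_rand`, plus `n` and `seed`.
#' @export
build_null_ensemble <- function(net, n = 100, seed = 1L, swap_factor = 10) {
  a <- as_adjacency(net)
  n_edges <- sum(a) / 2
  if (n_edges < 2)
    stop("null ensemble needs at least 2 edges", call. = FALSE)
  if (n < 1) stop("ensemble size must be >= 1", call. = FALSE)
  trials <- as.integer(swap_factor * n_edges)
  cp <- lp <- numeric(n)
  for (k in seq_len(n)) {
    r <- withr::with_seed(derive_seed(seed, k), .rewire_cpp(a, trials))
    m <- .cp_lp_cpp(r$adjacency)
    cp[k] <- m[1]
    lp[k] <- m[2]
  }
  structure(list(n = as.integer(n), Cp_rand = cp, Lp_rand = lp,
                 mean_Cp_rand = mean(cp), mean_Lp_rand = mean(lp),
                 seed = as.integer(seed)),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "<null_ensemble> %d rewired networks: mean Cp %.4g, mean Lp %.4g\n",
    x$n, x$mean_Cp_rand, x$mean_Lp_rand))
  invisible(x)
}

#' Small-world indices against a null ensemble
#'
#' `gamma = Cp_real / mean(Cp_rand)`, `lambda = Lp_real / mean(Lp_rand)`,
#' `sigma = gamma / lambda`. A network is flagged small-world when
#' `gamma > 1` and `sigma` exceeds `sigma_threshold` (default 1; 1.1 is
#' available as a stricter report threshold).
#'
#' @param real One-row tibble or list with `Cp` and `Lp` of the real
#'   network (e.g. from [global_metrics()]).
#' @param ensemble A `null_ensemble` from [build_null_ensemble()].
#' @param sigma_threshold Small-world criterion on sigma (default 1).
#' @return One-row tibble: `gamma`, `lambda`, `sigma`, `is_small_world`.
#' @export
small_world_indices <- function(real, ensemble, sigma_threshold = 1) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (ensemble$mean_Cp_rand <= 0 || ensemble$mean_Lp_rand <= 0 ||
      !is.finite(ensemble$mean_Cp_rand) || !is.finite(ensemble$mean_Lp_rand))
    stop("ensemble means must be positive and finite", call. = FALSE)
  gamma <- real$Cp / ensemble$mean_Cp_rand
  lambda <- real$Lp / ensemble$mean_Lp_rand
  sigma <- gamma / lambda
  tibble::tibble(gamma = gamma, lambda = lambda, sigma = sigma,
                 is_small_world = gamma > 1 & sigma > sigma_threshold)
}

#' Small-world index curves across a cost sweep
#'
#' For every cost in the sweep, computes the real network's Cp and Lp, a
#' degree-matched rewired null ensemble, and the normalized indices.
#'
#' @param sweep A `network_sweep`.
#' @param n_null Ensemble size per cost (default 100).
#' @param seed Integer master seed (per-cost seeds are derived).
#' @param swap_factor Attempted swaps per edge.
#' @param sigma_threshold Criterion passed to [small_world_indices()].
#' @return Tibble with one row per cost: `subject_id`, `cost`, `Cp`,
#'   `Lp`, `gamma`, `lambda`, `sigma`, `is_small_world`.
#' @export
small_world_curves <- function(sweep, n_null = 100, seed = 1L,
                               swap_factor = 10, sigma_threshold = 1) {
  stopifnot(inherits(sweep, "network_sweep"))
  rows <- purrr::map2_dfr(sweep$networks, seq_along(sweep$networks),
    function(net, k) {
      m <- .cp_lp_cpp(as_adjacency(net))
      real <- list(Cp = m[1], Lp = m[2])
      ens <- build_null_ensemble(net, n = n_null,
                                 seed = derive_seed(seed, k),
                                 swap_factor = swap_factor)
      out <- small_world_indices(real, ens, sigma_threshold)
      tibble::add_column(out, cost = net$cost, Cp = real$Cp, Lp = real$Lp,
                         .before = 1)
    })
  tibble::add_column(rows, subject_id = sweep$subject_id, .before = 1)
}
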