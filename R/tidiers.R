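#' Tidy a permutation test
#'
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return One-row tibble: `statistic` (observed pooled t), `p.value`
#'   (permutation p), `n.perm`, `n.a`, `n.b`, `significant`.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(statistic = x$t_observed, p.value = x$p_perm,
                 n.perm = x$n_permutations, n.a = x$n_a, n.b = x$n_b,
                 significant = x$significant)
}

#' @rdname tidy.perm_test
#' @export
glance.perm_test <- function(x, ...) tidy.perm_test(x, ...)

#' Tidy an edge-wise test result
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return The findings tibble (one row per reported edge).
#' @export
tidy.nbs_result <- function(x, ...) x$findings

#' @rdname tidy.nbs_result
#' @export
glance.nbs_result <- function(x, ...) {
  tibble::tibble(mode = x$mode,
                 n_findings = nrow(x$findings),
                 n_components = nrow(x$components),
                 n_significant_components =
                   if (nrow(x$components)) sum(x$components$significant)
                   else 0L,
                 primary_p = x$primary_p, alpha = x$alpha,
                 n_perm = x$n_perm)
}

#' Tidy a pipeline result
#'
#' @param x A `cohort_analysis` from [run_pipeline()].
#' @param ... Unused.
#' @return The global permutation-test table (one row per metric).
#' @export
tidy.cohort_analysis <- function(x, ...) x$global_tests

#' @rdname tidy.cohort_analysis
#' @export
glance.cohort_analysis <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$covariates),
    n_group_a = sum(x$covariates$group == "A"),
    n_group_b = sum(x$covariates$group == "B"),
    n_costs = length(x$config$costs),
    n_significant_global = sum(x$global_tests$significant),
    n_significant_nodes = if (is.null(x$nodal_tests)) NA_integer_
                          else sum(x$nodal_tests$significant),
    n_edge_findings = if (is.null(x$edge_result)) NA_integer_
                      else nrow(x$edge_result$findings))
}
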