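#' Area under a metric-versus-cost curve
#'
#' Trapezoidal integral of a metric over the cost grid, the standard
#' threshold-free scalar summary of a sweep.
#'
#' @param values Metric values, one per grid point.
#' @param costs Strictly increasing cost grid (defaults to
#'   [default_cost_grid()]).
#' @return Scalar AUC.
#' @export
metric_auc <- function(values, costs = default_cost_grid()) {
  if (length(values) != length(costs))
    stop("values and costs must have equal length", call. = FALSE)
  if (any(diff(costs) <= 0))
    stop("costs must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite metric value(s) at cost(s): ",
         paste(costs[!is.finite(values)], collapse = ", "), call. = FALSE)
  n <- length(values)
  sum(diff(costs) * (values[-1] + values[-n]) / 2)
}

#' Per-subject AUC summary of metric curves
#'
#' Collapses per-cost metric curves to one AUC scalar per subject and
#' metric. Every subject must have a value at every grid point; missing
#' costs are an error, never silently interpolated.
#'
#' @param curves Tibble from [metric_curves()] (or any tibble with
#'   `subject_id`, `cost`, and numeric metric columns).
#' @param costs The grid the curves must cover.
#' @param metrics Character vector of metric columns to summarize;
#'   default takes all numeric columns except `cost`.
#' @return Tibble: `subject_id`, `metric`, `auc`.
#' @export
auc_table <- function(curves, costs = default_cost_grid(), metrics = NULL) {
  stopifnot(is.data.frame(curves),
            all(c("subject_id", "cost") %in% names(curves)))
  if (is.null(metrics)) {
    num <- vapply(curves, is.numeric, logical(1))
    metrics <- setdiff(names(curves)[num], c("cost", "infinite_pairs"))
  }
  long <- tidyr::pivot_longer(
    curves[, c("subject_id", "cost", metrics)],
    cols = dplyr::all_of(metrics), names_to = "metric", values_to = "value")
  long |>
    dplyr::group_by(.data$subject_id, .data$metric) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$cost), ]
      if (length(df$cost) != length(costs) ||
          any(abs(df$cost - costs) > 1e-9))
        stop(sprintf("subject %s, metric %s: curve does not cover the grid",
                     key$subject_id, key$metric), call. = FALSE)
      tibble::tibble(auc = metric_auc(df$value, costs))
    }) |>
    dplyr::ungroup()
}

# Pooled-variance two-sample t statistics for every column of X.
# grp_a: logical vector over rows (TRUE = first group). Convention:
# t > 0 means the first group has the larger mean.
pooled_t <- function(x, grp_a) {
  x <- as.matrix(x)
  na <- sum(grp_a); nb <- sum(!grp_a)
  sa <- colSums(x[grp_a, , drop = FALSE])
  sb <- colSums(x[!grp_a, , drop = FALSE])
  qa <- colSums(x[grp_a, , drop = FALSE]^2)
  qb <- colSums(x[!grp_a, , drop = FALSE]^2)
  va <- (qa - sa^2 / na) / (na - 1)
  vb <- (qb - sb^2 / nb) / (nb - 1)
  s2p <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  num <- sa / na - sb / nb
  den <- sqrt(s2p * (1 / na + 1 / nb))
  t <- num / den
  t[den == 0] <- ifelse(num[den == 0] == 0, 0, sign(num[den == 0]) * Inf)
  t
}

# Permutation engine: observed pooled t per column of X plus, for each of
# n_perm seeded relabelings that preserve group sizes, the permuted t
# matrix (returned as a function applied per permutation to save memory).
perm_t_pvalues <- function(x, grp_a, n_perm, seed,
                           per_perm = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  t_obs <- pooled_t(x, grp_a)
  na <- sum(grp_a)
  exceed <- numeric(ncol(x))
  extra <- vector("list", if (is.null(per_perm)) 0 else n_perm)
  withr::with_seed(as.integer(seed), {
    for (p in seq_len(n_perm)) {
      idx <- sample.int(n, na)
      g <- logical(n); g[idx] <- TRUE
      tp <- pooled_t(x, g)
      exceed <- exceed + (abs(tp) >= abs(t_obs))
      if (!is.null(per_perm)) extra[[p]] <- per_perm(tp)
    }
  })
  list(t_obs = t_obs, p = (1 + exceed) / (n_perm + 1), extra = extra)
}

#' Two-sample permutation test on a scalar metric
#'
#' Pooled-variance two-sample t statistic (`mean(values_a) -
#' mean(values_b)` in the numerator), with significance assessed against
#' an empirical null built by randomly reassigning subjects to groups of
#' the original sizes. Two-sided p uses the add-one estimator `p = (1 +
#' #permutations with |t| >= |t_obs|) / (n_perm + 1)`, so p is never 0
#' and never below `1 / (n_perm + 1)`.
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed.
#' @param alpha Significance level for the `significant` flag.
#' @return A `perm_test` object; see [tidy()] for a one-row tibble.
#' @export
permutation_test <- function(values_a, values_b, n_perm = 5000, seed = 1L,
                             alpha = 0.05) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (any(!is.finite(c(values_a, values_b))))
    stop("values must be finite", call. = FALSE)
  if (var(values_a) == 0 && var(values_b) == 0 &&
      mean(values_a) == mean(values_b))
    stop("zero pooled variance: the test statistic is undefined",
         call. = FALSE)
  x <- matrix(c(values_a, values_b), ncol = 1)
  grp_a <- rep(c(TRUE, FALSE), c(length(values_a), length(values_b)))
  res <- perm_t_pvalues(x, grp_a, n_perm, seed)
  structure(list(t_observed = unname(res$t_obs), p_perm = unname(res$p),
                 n_permutations = as.integer(n_perm),
                 n_a = length(values_a), n_b = length(values_b),
                 alpha = alpha, significant = unname(res$p) < alpha,
                 seed = as.integer(seed)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> t = %.4g, p = %.4g (%d permutations, n = %d + %d)%s\n",
    x$t_observed, x$p_perm, x$n_permutations, x$n_a, x$n_b,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Region-wise permutation tests on nodal values
#'
#' Runs the same permutation engine on every region's values (typically
#' nodal-efficiency AUCs), sharing one set of seeded relabelings across
#' regions. The reported t statistic is group B minus group A, so
#' `direction = "increased"` means group B is higher.
#'
#' @param values Subjects x regions numeric matrix or data frame (column
#'   names are region labels).
#' @param group Character/factor vector of `"A"`/`"B"` per subject.
#' @param n_perm Number of permutations (default 5000).
#' @param alpha Per-region significance level (default 0.05).
#' @param seed Integer seed.
#' @return Tibble: `region`, `t_observed`, `p_perm`, `direction`,
#'   `significant`, ordered as the input columns.
#' @export
nodal_tests <- function(values, group, n_perm = 5000, alpha = 0.05,
                        seed = 1L) {
  x <- as.matrix(values)
  if (nrow(x) != length(group))
    stop("group must have one entry per row of values", call. = FALSE)
  grp_b <- group == "B"
  if (sum(grp_b) < 2 || sum(!grp_b) < 2)
    stop("each group needs at least 2 subjects", call. = FALSE)
  res <- perm_t_pvalues(x, grp_b, n_perm, seed)  # t = B - A
  tibble::tibble(
    region = colnames(x) %||% sprintf("R%03d", seq_len(ncol(x))),
    t_observed = unname(res$t_obs),
    p_perm = unname(res$p),
    direction = ifelse(res$t_obs > 0, "increased", "decreased"),
    significant = unname(res$p) < alpha
  )
}

#' Subjects-by-edges matrix of Fisher-z connectivity
#'
#' Stacks the upper triangle of each subject's z matrix into a row,
#' giving the pre-threshold edge values that edge-wise group tests
#' operate on.
#'
#' @param cms List of `connectivity_matrix` objects with identical
#'   region labels.
#' @return Numeric matrix (subjects x edges) with attributes `edge_i`,
#'   `edge_j` (1-based node indices) and `labels` (region labels).
#' @export
edge_matrix <- function(cms) {
  stopifnot(length(cms) >= 1)
  n <- nrow(cms[[1]]$z)
  up <- upper_pairs(n)
  x <- t(vapply(cms, function(cm) cm$z[up$idx], numeric(length(up$idx))))
  rownames(x) <- vapply(cms, function(cm) cm$subject_id, character(1))
  attr(x, "edge_i") <- up$i
  attr(x, "edge_j") <- up$j
  attr(x, "labels") <- rownames(cms[[1]]$z) %||% sprintf("R%03d", 1:n)
  x
}

# Union-find max component statistic over a set of suprathreshold edges.
# Returns list(sizes or masses per component, membership per edge).
edge_components <- function(ei, ej, weight = NULL) {
  if (length(ei) == 0)
    return(list(comp = integer(0), stat = numeric(0), edge_comp = integer(0)))
  nodes <- sort(unique(c(ei, ej)))
  id <- match(c(ei, ej), nodes)
  ii <- id[seq_along(ei)]
  jj <- id[-seq_along(ei)]
  parent <- seq_along(nodes)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (k in seq_along(ii)) {
    ra <- find(ii[k]); rb <- find(jj[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  edge_root <- vapply(ii, find, integer(1))
  comp_ids <- unique(edge_root)
  edge_comp <- match(edge_root, comp_ids)
  w <- weight %||% rep(1, length(ei))
  stat <- vapply(seq_along(comp_ids),
                 function(c) sum(w[edge_comp == c]), numeric(1))
  list(comp = comp_ids, stat = stat, edge_comp = edge_comp)
}

#' Edge-wise group tests with Bonferroni or NBS correction
#'
#' Per-edge pooled-t tests on pre-threshold Fisher-z values (group B
#' minus group A). `"bonferroni"` mode reports edges whose
#' Bonferroni-corrected parametric p is below `alpha`. `"nbs"` mode
#' (network-based statistic) thresholds edges at the primary level
#' `primary_p`, extracts connected components of suprathreshold edges,
#' and calibrates the component statistic (edge count by default, or sum
#' of |t| with `component_stat = "mass"`) against a permutation null of
#' the maximal component statistic.
#'
#' @param x Subjects x edges matrix from [edge_matrix()] (rows in the
#'   same order as `group`).
#' @param group `"A"`/`"B"` per subject.
#' @param primary_p Primary (per-edge, two-sided) threshold for NBS;
#'   default 0.005.
#' @param correction `"nbs"` or `"bonferroni"`.
#' @param alpha Component-level (NBS) or corrected (Bonferroni)
#'   significance level.
#' @param n_perm Permutations for the NBS null (default 5000).
#' @param seed Integer seed.
#' @param component_stat `"extent"` (edge count) or `"mass"` (sum |t|).
#' @return An `nbs_result` object: `findings` tibble (region_i,
#'   region_j, t, p, direction, component_id), `components` tibble, and
#'   the configuration used. `findings` is empty (zero rows) when
#'   nothing crosses the primary threshold.
#' @export
edgewise_tests <- function(x, group, primary_p = 0.005,
                           correction = c("nbs", "bonferroni"),
                           alpha = 0.05, n_perm = 5000, seed = 1L,
                           component_stat = c("extent", "mass")) {
  correction <- match.arg(correction)
  component_stat <- match.arg(component_stat)
  x <- as.matrix(x)
  ei <- attr(x, "edge_i"); ej <- attr(x, "edge_j")
  labels <- attr(x, "labels")
  if (is.null(ei) || is.null(ej))
    stop("x must carry edge_i/edge_j attributes (see edge_matrix())",
         call. = FALSE)
  grp_b <- group == "B"
  na <- sum(!grp_b); nb <- sum(grp_b)
  if (na < 2 || nb < 2)
    stop("each group needs at least 2 subjects", call. = FALSE)
  df <- na + nb - 2
  t_obs <- pooled_t(x, grp_b)  # B - A
  empty <- tibble::tibble(region_i = character(0), region_j = character(0),
                          t = numeric(0), p = numeric(0),
                          direction = character(0),
                          component_id = integer(0))
  if (correction == "bonferroni") {
    p_raw <- 2 * pt(-abs(t_obs), df)
    p_adj <- pmin(1, p_raw * length(t_obs))
    hit <- which(p_adj < alpha)
    findings <- if (length(hit) == 0) empty else tibble::tibble(
      region_i = labels[ei[hit]], region_j = labels[ej[hit]],
      t = t_obs[hit], p = p_adj[hit],
      direction = ifelse(t_obs[hit] > 0, "increased", "decreased"),
      component_id = NA_integer_)
    return(structure(list(findings = findings,
                          components = tibble::tibble(),
                          mode = "bonferroni", alpha = alpha,
                          primary_p = primary_p, n_perm = 0L),
                     class = "nbs_result"))
  }
  tcrit <- qt(1 - primary_p / 2, df)
  supra <- which(abs(t_obs) > tcrit)
  comp_obs <- edge_components(ei[supra], ej[supra],
                              weight = if (component_stat == "mass")
                                abs(t_obs[supra]) else NULL)
  # Null distribution of the maximal component statistic
  max_null <- numeric(n_perm)
  res <- perm_t_pvalues(x, grp_b, n_perm, seed, per_perm = function(tp) {
    s <- which(abs(tp) > tcrit)
    if (length(s) == 0) return(0)
    cc <- edge_components(ei[s], ej[s],
                          weight = if (component_stat == "mass")
                            abs(tp[s]) else NULL)
    max(cc$stat)
  })
  max_null <- unlist(res$extra)
  comp_p <- vapply(comp_obs$stat,
                   function(s) (1 + sum(max_null >= s)) / (n_perm + 1),
                   numeric(1))
  components <- tibble::tibble(
    component_id = seq_along(comp_obs$stat),
    n_edges = as.integer(tabulate(comp_obs$edge_comp,
                                  nbins = length(comp_obs$stat))),
    stat = comp_obs$stat,
    p_perm = comp_p,
    significant = comp_p < alpha)
  sig_comp <- which(components$significant)
  keep <- which(comp_obs$edge_comp %in% sig_comp)
  findings <- if (length(keep) == 0) empty else {
    k <- supra[keep]
    tibble::tibble(
      region_i = labels[ei[k]], region_j = labels[ej[k]],
      t = t_obs[k],
      p = comp_p[comp_obs$edge_comp[keep]],
      direction = ifelse(t_obs[k] > 0, "increased", "decreased"),
      component_id = comp_obs$edge_comp[keep])
  }
  structure(list(findings = findings, components = components,
                 mode = "nbs", alpha = alpha, primary_p = primary_p,
                 component_stat = component_stat,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> mode %s: %d finding(s)",
              x$mode, nrow(x$findings)))
  if (x$mode == "nbs")
    cat(sprintf(" in %d significant component(s) of %d",
                sum(x$components$significant %||% FALSE),
                nrow(x$components)))
  cat("\n")
  invisible(x)
}

#' Covariate-adjusted (partial) correlation
#'
#' Residualizes both variables on the covariates plus an intercept and
#' correlates the residuals; the p-value comes from the t distribution
#' with `n - 2 - k` degrees of freedom (k = number of covariates; with
#' the standard age + education adjustment, `n - 4`).
#'
#' @param x,y Numeric vectors (the network metric and the behavior).
#' @param covariates n x k numeric matrix or data frame.
#' @return One-row tibble: `estimate` (partial r), `statistic`,
#'   `p.value`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates) {
  cv <- as.matrix(covariates)
  n <- length(x)
  if (length(y) != n || nrow(cv) != n)
    stop("x, y and covariates must have matching lengths", call. = FALSE)
  if (n < 6)
    stop("need at least 6 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y) || anyNA(cv))
    stop("missing values are not allowed", call. = FALSE)
  design <- cbind(1, cv)
  qd <- qr(design)
  if (qd$rank < ncol(design))
    stop("covariate design is rank-deficient", call. = FALSE)
  rx <- qr.resid(qd, x)
  ry <- qr.resid(qd, y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("a variable is fully explained by the covariates", call. = FALSE)
  r <- cor(rx, ry)
  df <- n - 2 - ncol(cv)
  tstat <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  tibble::tibble(estimate = r, statistic = tstat,
                 p.value = 2 * pt(-abs(tstat), df),
                 df = df, n = n)
}
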