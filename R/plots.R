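#' Plot global metric curves across the cost sweep
#'
#' One line per subject, one panel per metric; the shape of these curves
#' (and their group separation) is what the AUC summaries integrate.
#'
#' @param curves Tibble from [metric_curves()] (stacked over subjects).
#' @param metrics Metric columns to show.
#' @param group Optional named vector (subject_id -> group) to color by.
#' @return A ggplot object.
#' @export
plot_metric_curves <- function(curves,
                               metrics = c("Cp", "Lp", "Eglobal", "Elocal"),
                               group = NULL) {
  long <- tidyr::pivot_longer(curves[, c("subject_id", "cost", metrics)],
                              cols = dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  if (!is.null(group)) long$group <- group[long$subject_id]
  p <- ggplot2::ggplot(long,
         ggplot2::aes(x = .data$cost, y = .data$value,
                      group = .data$subject_id)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "cost (network density)", y = NULL) +
    ggplot2::theme_minimal()
  if (is.null(group)) p + ggplot2::geom_line(alpha = 0.4)
  else p + ggplot2::geom_line(ggplot2::aes(color = .data$group), alpha = 0.5)
}

#' Plot small-world indices across the cost sweep
#'
#' Shows gamma, lambda and sigma per subject with the reference line at
#' 1; small-world networks sit above it for gamma and sigma while lambda
#' stays near it.
#'
#' @param sw Tibble from [small_world_curves()] (stacked over subjects).
#' @return A ggplot object.
#' @export
plot_small_world <- function(sw) {
  long <- tidyr::pivot_longer(sw[, c("subject_id", "cost", "gamma",
                                     "lambda", "sigma")],
                              cols = c("gamma", "lambda", "sigma"),
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cost, y = .data$value,
                                     group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "cost (network density)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot group comparison of AUC summaries
#'
#' @param auc Tibble from [auc_table()].
#' @param covariates Tibble with `subject_id` and `group`.
#' @return A ggplot object (boxplots by group, one panel per metric).
#' @export
plot_auc_comparison <- function(auc, covariates) {
  df <- dplyr::left_join(auc, covariates[, c("subject_id", "group")],
                         by = "subject_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$auc,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "AUC over cost grid") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
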