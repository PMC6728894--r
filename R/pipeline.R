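#' Configure a full pipeline run
#'
#' Bundles every knob of the analysis into one serializable object so a
#' run can be reproduced bit-for-bit from its configuration echo.
#'
#' @param mode `"synthetic"` (generate a cohort from `spec`) or
#'   `"directory"` (read subject TSVs from `input_dir`).
#' @param spec A [cohort_spec()] (synthetic mode).
#' @param input_dir Directory of subject TSVs plus `covariates.tsv`
#'   (directory mode).
#' @param costs Cost grid for the threshold sweep.
#' @param n_null Random networks per cost for small-world normalization;
#'   0 skips the small-world stage.
#' @param n_perm Permutations for all group tests.
#' @param alpha Significance level for global and nodal tests.
#' @param primary_p Primary edge-level threshold for NBS.
#' @param correction Edge-wise correction, `"nbs"` or `"bonferroni"`.
#' @param sigma_threshold Small-world report criterion on sigma.
#' @param bandpass Apply the temporal band-pass filter before
#'   connectivity.
#' @param low_hz,high_hz Band edges in Hz.
#' @param run_nodal,run_edges Toggle the nodal and edge-wise stages.
#' @param swap_factor Attempted swaps per edge in the null model.
#' @param seed Master seed for every stochastic stage.
#' @param out_dir If non-`NULL`, results are written here.
#' @return A `run_config` object.
#' @export
run_config <- function(mode = c("synthetic", "directory"),
                       spec = cohort_spec(), input_dir = NULL,
                       costs = default_cost_grid(), n_null = 100,
                       n_perm = 5000, alpha = 0.05, primary_p = 0.005,
                       correction = c("nbs", "bonferroni"),
                       sigma_threshold = 1, bandpass = TRUE,
                       low_hz = 0.01, high_hz = 0.08,
                       run_nodal = TRUE, run_edges = TRUE,
                       swap_factor = 10, seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  if (mode == "directory" && is.null(input_dir))
    stop("directory mode needs `input_dir`", call. = FALSE)
  if (mode == "synthetic") validate_cohort_spec(spec)
  if (any(costs <= 0 | costs >= 1) || any(diff(costs) <= 0))
    stop("costs must be strictly increasing within (0, 1)", call. = FALSE)
  structure(list(mode = mode, spec = spec, input_dir = input_dir,
                 costs = costs, n_null = n_null, n_perm = n_perm,
                 alpha = alpha, primary_p = primary_p,
                 correction = correction,
                 sigma_threshold = sigma_threshold, bandpass = bandpass,
                 low_hz = low_hz, high_hz = high_hz,
                 run_nodal = run_nodal, run_edges = run_edges,
                 swap_factor = swap_factor, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

stage_wrap <- function(stage, subject, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s'%s: %s", stage,
                 if (is.null(subject)) "" else paste0(", subject ", subject),
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes cohort generation (or ingestion), optional band-pass
#' filtering, connectivity-matrix construction, the cost-threshold
#' sweep, global and nodal metric curves, small-world normalization
#' against rewired null ensembles, AUC summarization, and permutation
#' group statistics (global metrics, nodal efficiency, edge-wise NBS or
#' Bonferroni, and duration-association partial correlations for group B
#' when duration covariates exist).
#'
#' @param config A [run_config()].
#' @return A `cohort_analysis` object: list of tibbles (`covariates`,
#'   `global_curves`, `small_world`, `auc`, `global_tests`,
#'   `nodal_tests`, `edge_result`, `behavior`) plus the config. When
#'   `config$out_dir` is set, results are also written as TSV/JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- stage_wrap("input", NULL,
    if (config$mode == "synthetic") simulate_cohort(config$spec)
    else read_timeseries_dir(config$input_dir))
  covars <- cohort$covariates
  if (is.null(covars) || is.null(covars$group))
    stop("stage 'input': covariates with a `group` column are required",
         call. = FALSE)
  ids <- vapply(cohort$subjects, function(s) s$subject_id, character(1))
  covars <- covars[match(ids, covars$subject_id), ]
  if (anyNA(covars$subject_id))
    stop("stage 'input': covariates are missing some subjects",
         call. = FALSE)

  prep <- lapply(cohort$subjects, function(ts)
    stage_wrap("signalprep", ts$subject_id,
               if (config$bandpass)
                 bandpass_filter(ts, config$low_hz, config$high_hz)
               else ts))

  cms <- lapply(prep, function(ts)
    stage_wrap("netbuild", ts$subject_id, fc_matrix(ts)))
  sweeps <- lapply(cms, function(cm)
    stage_wrap("netbuild", cm$subject_id, sweep_costs(cm, config$costs)))

  global_curves <- purrr::map_dfr(sweeps, function(sw)
    stage_wrap("graphmetrics", sw$subject_id, metric_curves(sw)))

  small_world <- NULL
  if (config$n_null > 0) {
    small_world <- purrr::imap_dfr(sweeps, function(sw, id)
      stage_wrap("nullmodels", id,
                 small_world_curves(
                   sw, n_null = config$n_null,
                   seed = derive_seed(config$seed,
                                      match(id, ids) * 1000L),
                   swap_factor = config$swap_factor,
                   sigma_threshold = config$sigma_threshold)))
  }

  auc <- stage_wrap("groupstats", NULL,
                    auc_table(global_curves, costs = config$costs,
                              metrics = c("Cp", "Lp", "Eglobal", "Elocal")))
  grp <- covars$group
  global_tests <- stage_wrap("groupstats", NULL,
    purrr::map_dfr(c("Cp", "Lp", "Eglobal", "Elocal"), function(m) {
      v <- auc$auc[auc$metric == m][match(ids, auc$subject_id[auc$metric == m])]
      va <- v[grp == "A"]; vb <- v[grp == "B"]
      pt_ <- permutation_test(vb, va,  # t > 0 means group B higher
                              n_perm = config$n_perm,
                              seed = derive_seed(config$seed,
                                                 match(m, c("Cp", "Lp",
                                                            "Eglobal",
                                                            "Elocal"))),
                              alpha = config$alpha)
      tibble::add_column(tidy(pt_), metric = m, .before = 1)
    }))

  nodal <- NULL
  if (config$run_nodal) {
    nodal_auc <- stage_wrap("groupstats", NULL, {
      nc <- purrr::map_dfr(sweeps, nodal_curves)
      wide <- nc |>
        dplyr::group_by(.data$subject_id, .data$region) |>
        dplyr::summarise(auc = metric_auc(.data$Enodal[order(.data$cost)],
                                          config$costs),
                         .groups = "drop") |>
        tidyr::pivot_wider(names_from = "region", values_from = "auc")
      m <- as.matrix(wide[, -1])
      rownames(m) <- wide$subject_id
      m[match(ids, rownames(m)), , drop = FALSE]
    })
    nodal <- stage_wrap("groupstats", NULL,
                        nodal_tests(nodal_auc, grp, n_perm = config$n_perm,
                                    alpha = config$alpha,
                                    seed = derive_seed(config$seed, 101L)))
  }

  edge_result <- NULL
  if (config$run_edges) {
    edge_result <- stage_wrap("groupstats", NULL,
      edgewise_tests(edge_matrix(cms), grp,
                     primary_p = config$primary_p,
                     correction = config$correction,
                     alpha = config$alpha, n_perm = config$n_perm,
                     seed = derive_seed(config$seed, 202L)))
  }

  behavior <- NULL
  if (!is.null(covars$duration_years) &&
      sum(grp == "B" & is.finite(covars$duration_years)) >= 6) {
    behavior <- stage_wrap("groupstats", NULL,
      purrr::map_dfr(c("Cp", "Lp", "Eglobal", "Elocal"), function(m) {
        sel <- grp == "B" & is.finite(covars$duration_years)
        v <- auc$auc[auc$metric == m][
          match(ids[sel], auc$subject_id[auc$metric == m])]
        pc <- partial_correlation(
          v, covars$duration_years[sel],
          cbind(age = covars$age_years[sel],
                education = covars$education_years[sel]))
        tibble::add_column(pc, metric = m, behavior = "duration_years",
                           .before = 1)
      }))
  }

  out <- structure(list(covariates = covars,
                        global_curves = global_curves,
                        small_world = small_world, auc = auc,
                        global_tests = global_tests,
                        nodal_tests = nodal, edge_result = edge_result,
                        behavior = behavior, config = config),
                   class = "cohort_analysis")
  if (!is.null(config$out_dir)) write_results(out, config$out_dir)
  out
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis>\n")
  cat(sprintf("  %d subjects, %d costs\n",
              nrow(x$covariates), length(x$config$costs)))
  print(x$global_tests)
  invisible(x)
}

write_results <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df))
      write.table(as.data.frame(df), file.path(dir, name), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  wt(analysis$covariates, "covariates.tsv")
  wt(analysis$global_curves, "metrics.tsv")
  wt(analysis$small_world, "small_world.tsv")
  wt(analysis$auc, "auc.tsv")
  wt(analysis$global_tests, "global_tests.tsv")
  wt(analysis$nodal_tests, "nodal_tests.tsv")
  wt(if (!is.null(analysis$edge_result)) analysis$edge_result$findings,
     "edge_findings.tsv")
  cfg <- analysis$config
  cfg$spec <- if (cfg$mode == "synthetic") unclass(cfg$spec) else NULL
  report <- list(
    config = unclass(cfg),
    global_tests = analysis$global_tests,
    nodal_significant = if (!is.null(analysis$nodal_tests))
      analysis$nodal_tests[analysis$nodal_tests$significant, ],
    edge_components = if (!is.null(analysis$edge_result))
      analysis$edge_result$components,
    behavior = analysis$behavior)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null", force = TRUE)
  invisible(dir)
}
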