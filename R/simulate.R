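#' Specify a synthetic two-group resting-state cohort
#'
#' Describes a cohort of "nonsmoker-like" (group A) and "smoker-like"
#' (group B) subjects whose ROI signals are drawn from a modular
#' correlation structure: `within_module_corr` inside each of `n_modules`
#' blocks, `between_module_corr` elsewhere. Group B's within-module
#' correlation is attenuated by `clustering_deficit` (a planted deficit in
#' local clustering) and additionally by `duration_effect *
#' duration_years` per subject, which plants a negative association
#' between smoking duration and clustering-type network metrics that the
#' analysis pipeline should recover.
#'
#' @param n_group_a,n_group_b Subjects per group.
#' @param n_rois Number of regions (nodes).
#' @param n_timepoints Retained volumes per subject.
#' @param tr_seconds Repetition time in seconds.
#' @param n_modules Number of correlation modules; regions are split into
#'   near-equal blocks, any remainder going to the last block.
#' @param within_module_corr,between_module_corr Block correlations; must
#'   satisfy `0 <= between < within < 1`.
#' @param clustering_deficit Fraction in `[0, 1)`: group B's within-module
#'   correlation is multiplied by `1 - clustering_deficit`.
#' @param duration_effect Per-year attenuation slope linking a group-B
#'   subject's smoking duration to extra within-module attenuation
#'   (multiplier `1 - duration_effect * duration_years`).
#' @param noise_sd Standard deviation of iid sensor noise added to the
#'   unit-variance structured signal; correlations attenuate by
#'   `1 / (1 + noise_sd^2)`.
#' @param ar_coef Optional AR(1) temporal smoothness of the latent
#'   signals, in `[0, 1)`; 0 (default) gives temporally white draws.
#' @param seed Master integer seed; the whole cohort is a pure function of
#'   this spec including the seed.
#' @return A `cohort_spec` object (validated list).
#' @seealso [simulate_cohort()], [build_group_covariance()]
#' @export
cohort_spec <- function(n_group_a = 30, n_group_b = 32, n_rois = 246,
                        n_timepoints = 170, tr_seconds = 2, n_modules = 6,
                        within_module_corr = 0.35,
                        between_module_corr = 0.05,
                        clustering_deficit = 0, duration_effect = 0,
                        noise_sd = 0.5, ar_coef = 0, seed = 1L) {
  spec <- list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    n_rois = as.integer(n_rois), n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, n_modules = as.integer(n_modules),
    within_module_corr = within_module_corr,
    between_module_corr = between_module_corr,
    clustering_deficit = clustering_deficit,
    duration_effect = duration_effect,
    noise_sd = noise_sd, ar_coef = ar_coef, seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    stopifnot(n_group_a >= 0, n_group_b >= 0, n_group_a + n_group_b >= 1,
              n_rois >= 2, n_timepoints >= 3, n_modules >= 1,
              n_modules <= n_rois)
    assert_scalar_number(tr_seconds, "tr_seconds", min = 1e-9)
    assert_scalar_number(within_module_corr, "within_module_corr",
                         min = 0, max = 1 - 1e-12)
    assert_scalar_number(between_module_corr, "between_module_corr", min = 0)
    if (between_module_corr >= within_module_corr)
      stop("between_module_corr must be < within_module_corr ",
           "(no modular structure otherwise)", call. = FALSE)
    assert_scalar_number(clustering_deficit, "clustering_deficit",
                         min = 0, max = 1 - 1e-12)
    assert_scalar_number(duration_effect, "duration_effect", min = 0)
    assert_scalar_number(noise_sd, "noise_sd", min = 0)
    assert_scalar_number(ar_coef, "ar_coef", min = 0, max = 1 - 1e-12)
  })
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d + %d subjects, %d ROIs x %d volumes (TR %gs)\n",
    x$n_group_a, x$n_group_b, x$n_rois, x$n_timepoints, x$tr_seconds))
  cat(sprintf(
    "  %d modules, corr within %.3g / between %.3g; deficit %.3g, duration slope %.3g\n",
    x$n_modules, x$within_module_corr, x$between_module_corr,
    x$clustering_deficit, x$duration_effect))
  cat(sprintf("  noise_sd %.3g, ar %.3g, seed %d\n",
              x$noise_sd, x$ar_coef, x$seed))
  invisible(x)
}

# Near-equal module assignment; remainder joins the last module.
module_assignment <- function(n_rois, n_modules) {
  base <- n_rois %/% n_modules
  sizes <- rep(base, n_modules)
  sizes[n_modules] <- sizes[n_modules] + n_rois - base * n_modules
  rep(seq_len(n_modules), times = sizes)
}

# Clip tiny negative eigenvalues to zero; genuinely negative ones are an
# error. Returns a correlation matrix (unit diagonal restored).
psd_clip <- function(m, tol = 1e-10) {
  eig <- eigen(m, symmetric = TRUE)
  lam <- eig$values
  if (any(lam < -tol))
    stop(sprintf("covariance is not positive semi-definite: eigenvalue %.3e",
                 min(lam)), call. = FALSE)
  if (any(lam < 0)) {
    message(sprintf("clipping %d eigenvalue(s) in [-%g, 0) to zero",
                    sum(lam < 0), tol))
    lam <- pmax(lam, 0)
    m <- eig$vectors %*% (lam * t(eig$vectors))
    m <- stats::cov2cor(m)
  }
  m
}

#' Build the modular correlation matrix for one group
#'
#' Block-structured correlation: `within_module_corr` inside modules,
#' `between_module_corr` elsewhere, unit diagonal. For group B the
#' within-module value is multiplied by `(1 - clustering_deficit)` and by
#' `(1 - duration_effect * duration)`; a negative product is clamped to
#' the between-module level with a warning. Eigenvalues in `[-1e-10, 0)`
#' are clipped to zero (with a message); anything lower is an error.
#'
#' @param spec A [cohort_spec()].
#' @param group `"A"` or `"B"`.
#' @param duration Smoking duration in years (group B); `NA` contributes
#'   no duration attenuation.
#' @return An `n_rois` x `n_rois` correlation matrix with a `"modules"`
#'   attribute giving each region's module index.
#' @export
build_group_covariance <- function(spec, group = c("A", "B"),
                                   duration = NA_real_) {
  spec <- validate_cohort_spec(spec)
  group <- match.arg(group)
  within <- spec$within_module_corr
  if (group == "B") {
    fac <- 1 - spec$clustering_deficit
    if (is.finite(duration)) fac <- fac * (1 - spec$duration_effect * duration)
    within <- within * fac
    if (within < spec$between_module_corr) {
      warning("attenuated within-module correlation fell below the ",
              "between-module level; clamping", call. = FALSE)
      within <- spec$between_module_corr
    }
  }
  mod <- module_assignment(spec$n_rois, spec$n_modules)
  same <- outer(mod, mod, "==")
  m <- matrix(spec$between_module_corr, spec$n_rois, spec$n_rois)
  m[same] <- within
  diag(m) <- 1
  m <- psd_clip(m)
  attr(m, "modules") <- mod
  m
}

#' Simulate one subject's ROI time series from a correlation structure
#'
#' Draws a T x N multivariate Gaussian via the symmetric matrix square
#' root of `cov` (eigen factorization), optionally AR(1)-smoothed in
#' time, adds iid Gaussian noise of standard deviation `noise_sd`, and
#' column-standardizes the result (mean 0, sd 1 per region). With
#' standardized output the expected sample correlation of a pair with
#' structural correlation `c` is `c / (1 + noise_sd^2)`.
#'
#' @param cov N x N positive semi-definite correlation/covariance matrix.
#' @param n_timepoints Number of time points (>= 3).
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param tr_seconds Repetition time recorded on the output.
#' @param subject_id Identifier for the output object.
#' @param region_labels Optional labels (defaults to `R001...`).
#' @param ar_coef AR(1) coefficient of the latent innovations, `[0, 1)`.
#' @return An [roi_timeseries()].
#' @export
simulate_subject <- function(cov, n_timepoints, noise_sd = 0.5, seed = 1L,
                             tr_seconds = 2, subject_id = "sub-001",
                             region_labels = NULL, ar_coef = 0) {
  if (n_timepoints < 3)
    stop("n_timepoints must be at least 3 (correlation undefined below)",
         call. = FALSE)
  n <- nrow(cov)
  eig <- eigen(cov, symmetric = TRUE)
  if (min(eig$values) < -1e-10)
    stop(sprintf("cov is not positive semi-definite: eigenvalue %.3e",
                 min(eig$values)), call. = FALSE)
  fac <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), n)
  withr::with_seed(as.integer(seed), {
    z <- matrix(rnorm(n_timepoints * n), n_timepoints, n)
    if (ar_coef > 0) {
      z <- apply(z, 2, function(col)
        as.numeric(stats::filter(col * sqrt(1 - ar_coef^2), ar_coef,
                                 method = "recursive")))
    }
    x <- z %*% t(fac)
    if (noise_sd > 0)
      x <- x + noise_sd * matrix(rnorm(n_timepoints * n), n_timepoints, n)
  })
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  roi_timeseries(x, subject_id = subject_id, tr_seconds = tr_seconds,
                 region_labels = region_labels)
}

#' Simulate a full two-group cohort
#'
#' Generates `n_group_a + n_group_b` subjects. Group-B smoking durations
#' are lognormal (median 4.5 years, log-sd 0.5, echoing a young-adult
#' smoker cohort); ages and education years are drawn from the same
#' distributions for both groups so the groups are matched in
#' expectation. Each subject's series is drawn with a seed derived from
#' the spec's master seed, so the cohort is a pure function of the spec.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort` object: list with `subjects` (named list of
#'   [roi_timeseries()]), `covariates` (tibble: subject_id, group,
#'   age_years, education_years, duration_years, seed), and `spec`.
#' @export
simulate_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  n_a <- spec$n_group_a
  n_b <- spec$n_group_b
  n <- n_a + n_b
  ids <- sprintf("sub-%03d", seq_len(n))
  grp <- rep(c("A", "B"), c(n_a, n_b))
  covars <- withr::with_seed(derive_seed(spec$seed, 0), {
    tibble::tibble(
      subject_id = ids,
      group = grp,
      age_years = round(rnorm(n, mean = 21, sd = 1.8), 1),
      education_years = round(rnorm(n, mean = 13, sd = 1.5), 1),
      duration_years = ifelse(
        grp == "B",
        round(rlnorm(n, meanlog = log(4.5), sdlog = 0.5), 2),
        NA_real_)
    )
  })
  covars$seed <- vapply(seq_len(n), function(i) derive_seed(spec$seed, i),
                        integer(1))
  labels <- sprintf("R%03d", seq_len(spec$n_rois))
  cov_a <- if (n_a > 0) build_group_covariance(spec, "A") else NULL
  subjects <- vector("list", n)
  names(subjects) <- ids
  for (i in seq_len(n)) {
    cv <- if (grp[i] == "A") cov_a
          else build_group_covariance(spec, "B",
                                      duration = covars$duration_years[i])
    subjects[[i]] <- simulate_subject(
      cv, spec$n_timepoints, noise_sd = spec$noise_sd,
      seed = covars$seed[i], tr_seconds = spec$tr_seconds,
      subject_id = ids[i], region_labels = labels, ar_coef = spec$ar_coef)
  }
  structure(list(subjects = subjects, covariates = covars, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d A, %d B), %d ROIs x %d volumes\n",
              length(x$subjects), sum(x$covariates$group == "A"),
              sum(x$covariates$group == "B"),
              x$spec$n_rois, x$spec$n_timepoints))
  invisible(x)
}

#' Simulate a nuisance-regressor set for testing
#'
#' Emulates the 14-column nuisance design used in resting-state
#' preprocessing: `n_motion` smooth random-walk "motion" traces, their
#' first-order temporal derivatives, and two slow "tissue" signals (white
#' matter, CSF stand-ins).
#'
#' @param n_timepoints Number of rows.
#' @param seed Integer seed.
#' @param n_motion Number of motion traces (default 6, giving 14 columns
#'   in total).
#' @return A T x (2 * n_motion + 2) numeric matrix with named columns.
#' @export
simulate_nuisance <- function(n_timepoints, seed = 1L, n_motion = 6) {
  withr::with_seed(as.integer(seed), {
    motion <- vapply(seq_len(n_motion), function(i)
      cumsum(rnorm(n_timepoints, sd = 0.05)), numeric(n_timepoints))
    deriv <- rbind(0, diff(motion))
    tissue <- vapply(1:2, function(i) {
      raw <- cumsum(rnorm(n_timepoints))
      as.numeric(stats::filter(raw, rep(1 / 5, 5), sides = 2,
                               circular = TRUE))
    }, numeric(n_timepoints))
    out <- cbind(motion, deriv, tissue)
    colnames(out) <- c(sprintf("motion%d", seq_len(n_motion)),
                       sprintf("motion%d_deriv", seq_len(n_motion)),
                       "white_matter", "csf")
    out
  })
}
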