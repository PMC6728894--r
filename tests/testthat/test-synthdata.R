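spec_small <- function(...) {
  cohort_spec(n_group_a = 3, n_group_b = 2, n_rois = 20, n_timepoints = 60,
              n_modules = 4, within_module_corr = 0.3,
              between_module_corr = 0.05, seed = 42, ...)
}

test_that("group covariance follows the block construction element-wise", {
  spec <- spec_small(clustering_deficit = 0.2)
  # group A ignores the deficit entirely
  expect_identical(build_group_covariance(spec, "A"),
                   build_group_covariance(spec_small(), "A"))
  # direct element-wise oracle for group B with deficit 0.2, within 0.3
  m <- build_group_covariance(spec, "B")
  mod <- attr(m, "modules")
  same <- outer(mod, mod, "==") & !diag(TRUE, 20)
  expect_true(all(abs(m[same] - 0.3 * 0.8) < 1e-12))
  expect_true(all(abs(m[same] - 0.24) < 1e-12))
  expect_true(all(abs(m[!same & !diag(TRUE, 20)] - 0.05) < 1e-12))
  expect_true(all(diag(m) == 1))
})

test_that("a single module gives an equicorrelation matrix", {
  spec <- cohort_spec(n_group_a = 1, n_group_b = 1, n_rois = 12,
                      n_timepoints = 30, n_modules = 1,
                      within_module_corr = 0.3, between_module_corr = 0.0)
  m <- build_group_covariance(spec, "A")
  off <- m[row(m) != col(m)]
  expect_true(all(off == 0.3))
})

test_that("duration attenuates group-B within-module correlation multiplicatively", {
  spec <- spec_small(clustering_deficit = 0.1, duration_effect = 0.02)
  m <- build_group_covariance(spec, "B", duration = 5)
  mod <- attr(m, "modules")
  same <- outer(mod, mod, "==") & !diag(TRUE, 20)
  expect_equal(unique(round(m[same], 12)), 0.3 * 0.9 * (1 - 0.02 * 5))
  # missing duration contributes no attenuation
  m_na <- build_group_covariance(spec, "B", duration = NA)
  expect_true(all(abs(m_na[same] - 0.27) < 1e-12))
})

test_that("module sizes are near-equal with the remainder in the last module", {
  mod <- costnet:::module_assignment(246, 6)
  expect_equal(length(mod), 246)
  expect_equal(as.integer(table(mod)), rep(41L, 6))
  mod2 <- costnet:::module_assignment(20, 3)
  expect_equal(as.integer(table(mod2)), c(6L, 6L, 8L))
})

test_that("PSD repair clips tiny negatives and rejects real ones", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 1 - 1e-13  # eigenvalue ~1e-13 above 0, fine
  expect_silent(costnet:::psd_clip(m))
  bad <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.9, 0.1, 0.9, 1), 3)
  expect_error(costnet:::psd_clip(bad, tol = 1e-10), "eigenvalue")
})

test_that("simulate_subject is deterministic and respects the target covariance", {
  a <- simulate_subject(diag(8), 50, noise_sd = 0.3, seed = 5)
  b <- simulate_subject(diag(8), 50, noise_sd = 0.3, seed = 5)
  expect_identical(a$values, b$values)
  expect_error(simulate_subject(diag(8), 2, seed = 1), "at least 3")

  # identity covariance, no noise: off-diagonal correlations ~ 0 (+/- 1/sqrt(T))
  ts <- simulate_subject(diag(12), 10000, noise_sd = 0, seed = 11)
  r <- cor(ts$values)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)

  # block covariance with noise: attenuation = c / (1 + noise_sd^2)
  spec <- cohort_spec(n_group_a = 1, n_group_b = 1, n_rois = 10,
                      n_timepoints = 5000, n_modules = 1,
                      within_module_corr = 0.6, between_module_corr = 0)
  cv <- build_group_covariance(spec, "A")
  ts2 <- simulate_subject(cv, 5000, noise_sd = 0.5, seed = 3)
  r2 <- cor(ts2$values)
  target <- 0.6 / (1 + 0.25)
  expect_lt(max(abs(r2[upper.tri(r2)] - target)), 0.05)
})

test_that("columns are standardized and AR smoothing preserves unit variance", {
  ts <- simulate_subject(diag(6), 400, noise_sd = 0.2, seed = 9,
                         ar_coef = 0.4)
  expect_equal(unname(colMeans(ts$values)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(ts$values, 2, sd)), rep(1, 6), tolerance = 1e-12)
})

test_that("simulate_cohort produces the requested records and covariates", {
  spec <- spec_small()
  co <- simulate_cohort(spec)
  expect_length(co$subjects, 5)
  expect_equal(sum(co$covariates$group == "A"), 3)
  expect_true(all(is.na(co$covariates$duration_years[co$covariates$group == "A"])))
  expect_true(all(is.finite(co$covariates$duration_years[co$covariates$group == "B"])))
  expect_true(all(vapply(co$subjects, function(s)
    identical(dim(s$values), c(60L, 20L)), logical(1))))
  # pure function of the spec
  co2 <- simulate_cohort(spec)
  expect_identical(co$subjects[["sub-004"]]$values,
                   co2$subjects[["sub-004"]]$values)
  expect_identical(co$covariates, co2$covariates)
})

test_that("clustering deficit lowers group-B within-module sample correlation", {
  mean_within <- function(deficit, seed) {
    spec <- cohort_spec(n_group_a = 0, n_group_b = 1, n_rois = 24,
                        n_timepoints = 150, n_modules = 4,
                        within_module_corr = 0.4,
                        between_module_corr = 0.05,
                        clustering_deficit = deficit, seed = seed)
    co <- simulate_cohort(spec)
    r <- cor(co$subjects[[1]]$values)
    mod <- costnet:::module_assignment(24, 4)
    same <- outer(mod, mod, "==") & upper.tri(r)
    mean(r[same])
  }
  diffs <- vapply(1:20, function(s)
    mean_within(0.3, s) - mean_within(0, s), numeric(1))
  expect_lt(mean(diffs), 0)
  expect_gt(mean(diffs < 0), 0.8)
})

test_that("covariates round-trip losslessly through the TSV writer", {
  co <- simulate_cohort(spec_small())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_covariates_tsv(co$covariates, path)
  back <- read_covariates_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(co$covariates))
})

test_that("spec invariants are enforced", {
  expect_error(cohort_spec(between_module_corr = 0.5,
                           within_module_corr = 0.3), "modular")
  expect_error(cohort_spec(clustering_deficit = 1.2), "clustering_deficit")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd")
})
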