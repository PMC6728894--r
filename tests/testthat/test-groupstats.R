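test_that("trapezoidal AUC is exact on constants, lines and random knots", {
  grid <- default_cost_grid()
  expect_equal(metric_auc(rep(2.5, 31), grid), 0.30 * 2.5)
  lin <- seq(1, 4, length.out = 31)
  expect_equal(metric_auc(lin, grid), 0.30 * (1 + 4) / 2)
  set.seed(10)
  v <- rnorm(31)
  # independent trapezoid oracle on the same knots
  oracle <- sum(vapply(1:30, function(k)
    (grid[k + 1] - grid[k]) * (v[k] + v[k + 1]) / 2, numeric(1)))
  expect_equal(metric_auc(v, grid), oracle, tolerance = 1e-12)
  expect_error(metric_auc(c(1, NA, rep(1, 29)), grid), "non-finite")
  expect_error(metric_auc(1:5, grid), "equal length")
})

test_that("auc_table refuses curves that miss grid points", {
  curves <- tibble::tibble(subject_id = "s1",
                           cost = c(0.1, 0.2), Cp = c(1, 2))
  expect_error(auc_table(curves, costs = c(0.1, 0.2, 0.3)),
               "does not cover")
  ok <- auc_table(curves, costs = c(0.1, 0.2), metrics = "Cp")
  expect_equal(ok$auc, 0.1 * 1.5)
})

test_that("permutation test behaves on identical and fully separated groups", {
  pt1 <- permutation_test(1:10, 1:10, n_perm = 500, seed = 1)
  expect_equal(pt1$t_observed, 0)
  expect_gt(pt1$p_perm, 0.9)

  set.seed(2)
  a <- rnorm(15, 10, 0.1); b <- rnorm(15, 0, 0.1)
  pt2 <- permutation_test(a, b, n_perm = 1000, seed = 3)
  expect_equal(pt2$p_perm, 1 / 1001)  # attainable minimum (add-one)
  expect_true(pt2$significant)
  expect_gte(pt2$p_perm, 1 / (pt2$n_permutations + 1))

  expect_error(permutation_test(rep(1, 5), rep(1, 5)), "zero pooled")
  expect_error(permutation_test(1, 1:3), "at least 2")
  td <- tidy(pt2)
  expect_named(td, c("statistic", "p.value", "n.perm", "n.a", "n.b",
                     "significant"))
})

test_that("permutation p-values are invariant to swapping group labels", {
  set.seed(4)
  a <- rnorm(12); b <- rnorm(12, 0.5)
  p1 <- permutation_test(a, b, n_perm = 2000, seed = 5)$p_perm
  p2 <- permutation_test(b, a, n_perm = 2000, seed = 5)$p_perm
  expect_equal(p1, p2, tolerance = 0.05)
  t1 <- permutation_test(a, b, n_perm = 10, seed = 5)$t_observed
  t2 <- permutation_test(b, a, n_perm = 10, seed = 5)$t_observed
  expect_equal(t1, -t2, tolerance = 1e-12)
})

test_that("permutation test type-I error is calibrated at alpha = 0.05", {
  rejections <- vapply(1:500, function(s) {
    set.seed(s + 9000)
    a <- rnorm(15); b <- rnorm(15)
    permutation_test(a, b, n_perm = 199, seed = s)$p_perm < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("a single-region table reduces to permutation_test", {
  set.seed(6)
  vals <- matrix(rnorm(20), ncol = 1, dimnames = list(NULL, "only"))
  grp <- rep(c("B", "A"), each = 10)  # same row layout as the scalar test
  nt <- nodal_tests(vals, grp, n_perm = 500, seed = 7)
  pt <- permutation_test(vals[grp == "B"], vals[grp == "A"],
                         n_perm = 500, seed = 7)
  expect_equal(nt$t_observed, pt$t_observed, tolerance = 1e-12)
  expect_equal(nt$p_perm, pt$p_perm)
})

test_that("nodal tests recover implanted regions and stay calibrated under the null", {
  n_regions <- 40
  implant <- c(3, 11, 19, 27, 35)
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(30 * n_regions), 30, n_regions)
    x[16:30, implant] <- x[16:30, implant] + 1.5
    grp <- rep(c("A", "B"), each = 15)
    nt <- nodal_tests(x, grp, n_perm = 500, alpha = 0.05, seed = s)
    mean(nt$significant[implant] & nt$direction[implant] == "increased")
  }, numeric(1))
  expect_gte(mean(hits), 0.8)  # power over implanted regions

  # pure null: false-positive count within the binomial 95% band
  set.seed(123)
  x0 <- matrix(rnorm(30 * 100), 30, 100)
  nt0 <- nodal_tests(x0, rep(c("A", "B"), each = 15), n_perm = 500,
                     seed = 11)
  fp <- sum(nt0$significant)
  band <- qbinom(c(0.025, 0.975), 100, 0.05)
  expect_gte(fp, band[1])
  expect_lte(fp, band[2])
})

test_that("edgewise NBS recovers an implanted connected component", {
  n <- 12
  up <- costnet:::upper_pairs(n)
  # implant: a 6-edge path component among nodes 1..6 (wait: path of 6 edges)
  comp_edges <- cbind(c(1, 2, 3, 4, 5, 1), c(2, 3, 4, 5, 6, 3))
  edge_id <- function(i, j) which(up$i == pmin(i, j) & up$j == pmax(i, j))
  implant <- mapply(edge_id, comp_edges[, 1], comp_edges[, 2])
  recovered <- vapply(1:20, function(s) {
    set.seed(s + 50)
    x <- matrix(rnorm(30 * length(up$i), sd = 0.3), 30)
    x[16:30, implant] <- x[16:30, implant] + 0.8
    attr(x, "edge_i") <- up$i; attr(x, "edge_j") <- up$j
    attr(x, "labels") <- sprintf("R%03d", 1:n)
    res <- edgewise_tests(x, rep(c("A", "B"), each = 15),
                          primary_p = 0.005, correction = "nbs",
                          alpha = 0.05, n_perm = 200, seed = s)
    f <- res$findings
    if (nrow(f) == 0) return(0)
    found <- paste(f$region_i, f$region_j)
    want <- paste(sprintf("R%03d", pmin(comp_edges[, 1], comp_edges[, 2])),
                  sprintf("R%03d", pmax(comp_edges[, 1], comp_edges[, 2])))
    sum(want %in% found)
  }, numeric(1))
  expect_gte(mean(recovered >= 5), 0.8)
})

test_that("edgewise tests return an empty finding list when nothing crosses", {
  n <- 8
  up <- costnet:::upper_pairs(n)
  set.seed(99)
  x <- matrix(rnorm(20 * length(up$i)), 20)
  attr(x, "edge_i") <- up$i; attr(x, "edge_j") <- up$j
  attr(x, "labels") <- sprintf("R%03d", 1:n)
  res <- edgewise_tests(x, rep(c("A", "B"), each = 10),
                        primary_p = 1e-8, correction = "nbs",
                        n_perm = 50, seed = 1)
  expect_equal(nrow(res$findings), 0)
  resb <- edgewise_tests(x, rep(c("A", "B"), each = 10),
                         correction = "bonferroni", alpha = 1e-6)
  expect_equal(nrow(resb$findings), 0)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$n_findings, 0L)
})

test_that("bonferroni mode flags a strong single edge", {
  n <- 8
  up <- costnet:::upper_pairs(n)
  set.seed(3)
  x <- matrix(rnorm(30 * length(up$i), sd = 0.2), 30)
  x[16:30, 5] <- x[16:30, 5] + 3
  attr(x, "edge_i") <- up$i; attr(x, "edge_j") <- up$j
  attr(x, "labels") <- sprintf("R%03d", 1:n)
  res <- edgewise_tests(x, rep(c("A", "B"), each = 15),
                        correction = "bonferroni", alpha = 0.05)
  expect_equal(nrow(res$findings), 1)
  expect_equal(res$findings$direction, "increased")
  expect_equal(res$findings$region_i,
               sprintf("R%03d", up$i[5]))
})

test_that("partial correlation matches a two-stage least-squares oracle", {
  set.seed(12)
  n <- 40
  cov2 <- cbind(age = rnorm(n, 21), edu = rnorm(n, 13))
  x <- rnorm(n) + 0.3 * cov2[, 1]
  y <- -0.5 * x + rnorm(n, sd = 0.5) + 0.2 * cov2[, 2]
  pc <- partial_correlation(x, y, cov2)
  # oracle: residuals from explicit normal equations, then cor + t test
  d <- cbind(1, cov2)
  rx <- x - d %*% solve(t(d) %*% d, t(d) %*% x)
  ry <- y - d %*% solve(t(d) %*% d, t(d) %*% y)
  r_o <- cor(rx, ry)[1, 1]
  expect_equal(pc$estimate, r_o, tolerance = 1e-10)
  expect_equal(pc$df, n - 4)
  t_o <- r_o * sqrt((n - 4) / (1 - r_o^2))
  expect_equal(pc$statistic, t_o, tolerance = 1e-10)
  expect_equal(pc$p.value, 2 * pt(-abs(t_o), n - 4), tolerance = 1e-12)
})

test_that("exact linear dependence gives partial r = -1", {
  set.seed(13)
  n <- 20
  cv <- matrix(rnorm(n * 2), n)
  x <- qr.resid(qr(cbind(1, cv)), rnorm(n))  # orthogonal to covariates
  y <- -2 * x
  pc <- partial_correlation(x, y, cv)
  expect_equal(pc$estimate, -1, tolerance = 1e-12)
  expect_error(partial_correlation(x[1:5], y[1:5], cv[1:5, ]), "at least 6")
  expect_error(partial_correlation(x, y, cbind(cv, cv[, 1])),
               "rank-deficient")
})

test_that("partial correlation rejects at ~0.05 under the null", {
  rej <- vapply(1:500, function(s) {
    set.seed(s + 4000)
    cv <- matrix(rnorm(30 * 2), 30)
    partial_correlation(rnorm(30), rnorm(30), cv)$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})
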