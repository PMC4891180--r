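make_profile <- function(d, ...) summarize_cohort(d, ...)

test_that("distance to surface handles exact and axis-aligned geometry", {
  surf <- data.frame(x_um = c(0, 0), y_um = c(-10, 110))
  coh <- new_cell_cohort(
    data.frame(cell_id = c("a", "b"), x_um = c(0, 30), y_um = c(-10, 17)),
    "demo", surf)
  expect_equal(distance_to_surface(coh), c(0, 30))
})

test_that("distance to surface matches a dense-resampling oracle", {
  set.seed(101)
  surf <- data.frame(x_um = c(0, 15, 20, 50, 80),
                     y_um = c(0, 30, 70, 90, 85))
  cells <- data.frame(cell_id = sprintf("c%02d", 1:20),
                      x_um = runif(20, -20, 100), y_um = runif(20, -20, 120))
  got <- distance_to_surface(new_cell_cohort(cells, "demo", surf))
  want <- oracle_surface_distance(cells$x_um, cells$y_um,
                                  surf$x_um, surf$y_um)
  expect_equal(got, want, tolerance = 1e-3)
  expect_true(all(got >= 0))
})

test_that("distances are invariant under joint rigid rotation/translation", {
  set.seed(102)
  surf <- data.frame(x_um = c(0, 10, 30), y_um = c(0, 40, 60))
  cells <- data.frame(cell_id = sprintf("c%02d", 1:15),
                      x_um = runif(15, -10, 60), y_um = runif(15, -10, 80))
  d0 <- distance_to_surface(new_cell_cohort(cells, "demo", surf))
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(x, y) cbind(x, y) %*% t(R) + matrix(c(7, -3), nrow = length(x),
                                                      ncol = 2, byrow = TRUE)
  cr <- rot(cells$x_um, cells$y_um); sr <- rot(surf$x_um, surf$y_um)
  d1 <- distance_to_surface(new_cell_cohort(
    data.frame(cell_id = cells$cell_id, x_um = cr[, 1], y_um = cr[, 2]),
    "demo", data.frame(x_um = sr[, 1], y_um = sr[, 2])))
  expect_equal(d1, d0, tolerance = 1e-6)
})

test_that("cohort summaries match direct statistics and the percentile oracle", {
  pr <- make_profile(rep(42, 25))
  expect_equal(pr$mean_um, 42)
  expect_equal(pr$sd_um, 0)
  expect_equal(pr$p99_um, 42)
  expect_equal(sum(pr$counts), pr$n)

  pr2 <- make_profile(as.numeric(1:100))
  expect_equal(pr2$p99_um, oracle_percentile(1:100, 0.99))
  expect_equal(sum(pr2$counts), 100)
  expect_gte(pr2$p99_um, median(pr2$distances))
  expect_error(summarize_cohort(numeric(0)), "empty")
})

test_that("chi-square comparison matches hand formula and is symmetric", {
  # identical histograms: statistic exactly 0, p exactly 1
  d <- runif(500, 0, 200)
  pa <- make_profile(d)
  same <- compare_distributions(pa, pa)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # two-bin case against the direct 2x2 formula
  a <- make_profile(c(rep(5, 10), rep(15, 90)), bin_width_um = 10,
                    domain_max_um = 20)
  b <- make_profile(c(rep(5, 50), rep(15, 50)), bin_width_um = 10,
                    domain_max_um = 20)
  got <- compare_distributions(a, b)
  expect_equal(got$statistic, oracle_chi2_2x2(10, 90, 50, 50), tolerance = 1e-12)
  expect_equal(got$p_value, pchisq(got$statistic, 1, lower.tail = FALSE))

  ba <- compare_distributions(b, a)
  expect_equal(ba$statistic, got$statistic)
  expect_equal(ba$p_value, got$p_value)

  expect_error(compare_distributions(a, make_profile(d)), "bin edges")
})

test_that("bin merging preserves totals and yields usable tables", {
  set.seed(103)
  pa <- make_profile(rnorm(400, 60, 15))
  pb <- make_profile(rnorm(300, 80, 20))
  res <- compare_distributions(pa, pb)
  expect_gte(res$statistic, 0)
  expect_equal(res$df, res$n_bins_used - 1L)
  m <- gzexit:::merge_low_expected(rbind(pa$counts, pb$counts))
  expect_equal(sum(m), 700)
  expect_true(all(colSums(m) > 0))
})

test_that("chi-square p-values are calibrated for same-preset cohorts", {
  p <- cohort_preset("cal", mean_um = 70, sd_um = 15, n_cells = 1000)
  pv <- vapply(1:100, function(s) {
    a <- make_profile(distance_to_surface(generate_cohort(p, seed = 2 * s)))
    b <- make_profile(distance_to_surface(generate_cohort(p, seed = 2 * s + 1)))
    compare_distributions(a, b)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("Welch t matches the long-hand formula and published summaries", {
  expect_equal(welch_t(10, 2, 30, 10, 2, 30), list(t = 0, df = 58, p_value = 1))

  # printed 24 h control vs Zeb1-silenced summaries separate at p < 0.01
  expect_lt(welch_t(34.2, 10.1, 7358, 67.5, 18.1, 4693)$p_value, 0.01)

  set.seed(104)
  xa <- rnorm(12, 5, 2); xb <- rnorm(17, 6.5, 3)
  got <- welch_t(xa, mean_b = xb)
  want <- oracle_welch(xa, xb)
  expect_equal(got$t, want$t, tolerance = 1e-9)
  expect_equal(got$df, want$df, tolerance = 1e-9)
  expect_equal(got$p_value, want$p, tolerance = 1e-9)
  tt <- t.test(xa, xb)
  expect_equal(got$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(got$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("rescue classification applies both criteria with default thresholds", {
  ctrl_p <- get_preset("fig6s1:control-48h")
  phen_p <- get_preset("fig6s1:Zeb1")
  ctrl <- make_profile(distance_to_surface(generate_cohort(ctrl_p, seed = 31)))
  phen <- make_profile(distance_to_surface(generate_cohort(phen_p, seed = 32)))
  # a test cohort that IS the control draw: chi2 p = 1, far from phenotype
  v1 <- classify_rescue(ctrl, phen, ctrl)
  expect_true(v1$rescued)
  expect_equal(v1$chi2_p_vs_control, 1)
  expect_lt(v1$t_p_vs_phenotype, 0.01)
  # the phenotype itself is never called rescued
  v2 <- classify_rescue(ctrl, phen, phen)
  expect_false(v2$rescued)
  expect_equal(v2$t_p_vs_phenotype, 1)
  # default thresholds are the published rule
  expect_equal(v1$chi2_threshold, 0.8)
  expect_equal(v1$t_threshold, 0.01)
})

test_that("rescue calls are monotone along a phenotype-to-control interpolation", {
  ctrl_p <- get_preset("fig6s1:control-48h")
  phen_p <- get_preset("fig6s1:Zeb1")
  ctrl <- make_profile(distance_to_surface(generate_cohort(ctrl_p, seed = 41)))
  phen <- make_profile(distance_to_surface(generate_cohort(phen_p, seed = 42)))
  calls <- vapply(seq(0, 1, by = 0.1), function(w) {
    mix <- cohort_preset("mix",
                         mean_um = (1 - w) * phen_p$mean_um + w * ctrl_p$mean_um,
                         sd_um = (1 - w) * phen_p$sd_um + w * ctrl_p$sd_um,
                         n_cells = 5000)
    test <- make_profile(distance_to_surface(generate_cohort(mix, seed = 43)))
    classify_rescue(ctrl, phen, test)$rescued
  }, logical(1))
  # once the interpolant is called rescued it stays rescued toward control
  expect_false(is.unsorted(calls))
})
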