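test_that("F-test profile on a straight line matches the analytic interval", {
  set.seed(5)
  x <- seq(0, 10, length.out = 12)
  y <- 2 + 0.7 * x + stats::rnorm(12, 0, 0.4)
  fit <- stats::lm(y ~ x)
  rss0 <- sum(stats::resid(fit)^2)
  slope <- stats::coef(fit)[["x"]]
  se <- summary(fit)$coefficients["x", "Std. Error"]
  grid <- seq(slope - 6 * se, slope + 6 * se, length.out = 401)
  prob <- vapply(grid, function(s) {
    a <- mean(y - s * x)  # closed-form re-fit of the intercept
    f_test_probability(sum((y - a - s * x)^2), rss0, length(y),
                       n_free = 2, n_fixed = 1)
  }, 0)
  lo <- max(grid[grid < slope & prob >= 0.95])
  hi <- min(grid[grid > slope & prob >= 0.95])
  ci <- stats::confint(fit, "x", level = 0.95)
  cell <- diff(grid)[1]
  expect_lt(abs(lo - ci[1]), cell)
  expect_lt(abs(hi - ci[2]), cell)
})

test_that("confidence surface is minimal at the best fit and transposes", {
  set.seed(99)
  cur <- add_noise(ivim_signal(gm_truth, sch11), noise_spec(20))
  fit <- fit_one_parameter(cur)
  g <- confidence_grid(cur, fit, c("f", "D_star"),
                       spec = method_spec("one_parameter"), n_grid = 21)
  expect_true(all(g$probability >= 0 & g$probability <= 1))
  i <- which.min(abs(g$axis1 - fit$estimate[["f"]]))
  j <- which.min(abs(g$axis2 - fit$estimate[["D_star"]]))
  expect_equal(g$probability[i, j], min(g$probability))
  gt <- confidence_grid(cur, fit, c("D_star", "f"),
                        spec = method_spec("one_parameter"), n_grid = 21)
  expect_equal(gt$probability, t(g$probability))
})

test_that("a perfect noiseless fit yields a degenerate surface error", {
  cur <- ivim_signal(gm_truth, sch11)
  fit <- fit_three_parameter(cur)
  expect_error(confidence_grid(cur, fit, c("f", "D_star")),
               "degenerate surface")
  expect_error(f_test_probability(1, 0, 11, 3), "degenerate surface")
})

test_that("low-SNR gray matter: the 95% region is elongated along D*", {
  set.seed(99)
  cur <- add_noise(ivim_signal(gm_truth, sch11), noise_spec(20))
  fit <- fit_one_parameter(cur)
  expect_false(fit$outlier)
  g <- confidence_grid(cur, fit, c("f", "D_star"),
                       spec = method_spec("one_parameter"),
                       span_stderr = 15, n_grid = 41)
  reg <- g$probability < 0.95
  ext_f <- diff(range(g$axis1[rowSums(reg) > 0])) / abs(fit$estimate[["f"]])
  ext_ds <- diff(range(g$axis2[colSums(reg) > 0])) /
    abs(fit$estimate[["D_star"]])
  expect_gt(ext_ds / ext_f, 2)
})

test_that("noiseless multi-start census finds the single true minimum", {
  cen <- minima_census(ivim_signal(tumor_truth, sch11), truth = tumor_truth)
  expect_equal(cen$n_starts, 27)
  expect_equal(cen$n_minima, 1)
  expect_equal(cen$solutions$D, tumor_truth$D, tolerance = 1e-6)
  expect_equal(cen$solutions$D_star, tumor_truth$D_star, tolerance = 1e-6)
  expect_equal(cen$solutions$f, tumor_truth$f, tolerance = 1e-6)
  expect_true(cen$global_is_correct)
})

test_that("census counts are non-increasing in the merge tolerance", {
  set.seed(21)
  cur <- add_noise(ivim_signal(tumor_truth, sch11), noise_spec(40))
  counts <- vapply(c(1e-5, 1e-3, 1e-1, 1), function(tol)
    minima_census(cur, merge_tol = tol)$n_minima, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("mirrored compartment solutions count as one minimum", {
  # (D, D*, f) and (D*, D, 1-f) trace identical curves; a census seeded from
  # both sides of the diagonal must not report the reflection as distinct
  set.seed(33)
  cur <- add_noise(ivim_signal(tumor_truth, sch11), noise_spec(60))
  cen <- minima_census(cur, truth = tumor_truth)
  if (!is.null(cen$solutions) && cen$n_minima >= 1) {
    expect_true(all(cen$solutions$D <= cen$solutions$D_star + 1e-12))
  }
})
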