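test_that("coefficient of variation matches hand-computed values", {
  expect_equal(cv_percent(c(10, 10, 10)), 0)
  expect_equal(cv_percent(c(9, 10, 11)), 10)  # sample SD 1, mean 10
  expect_error(cv_percent(c(5)), ">= 2")
  expect_error(cv_percent(c(-1, 1)), "mean of estimates is zero")
})

test_that("mean error percent measures the error of the ensemble mean", {
  th <- 1.63e-3
  expect_equal(mean_error_percent(rep(th, 5), th), 0)
  expect_equal(mean_error_percent(th * c(1.05, 0.95, 1.0), th), 0,
               tolerance = 1e-10)
  expect_equal(mean_error_percent(th * c(1.1, 1.1, 1.1), th), 10)
  expect_error(mean_error_percent(c(1, 2), 0), "nonzero")
})

test_that("Bland-Altman bias and limits of agreement", {
  th <- 10
  ba0 <- bland_altman(rep(th, 4), th)
  expect_equal(unlist(ba0), c(bias_percent = 0, loa_low = 0, loa_high = 0))
  # d = {-10, +10} percent: bias 0, sample SD 14.1421, LoA +/- 27.7186
  ba <- bland_altman(th * c(0.9, 1.1), th)
  expect_equal(ba$bias_percent, 0)
  expect_equal(ba$loa_high, 1.96 * stats::sd(c(-10, 10)))
  expect_equal(ba$loa_high, 27.71859, tolerance = 1e-6)
  expect_equal(ba$loa_low, -27.71859, tolerance = 1e-6)
})

test_that("outlier percent is a plain fraction of flags", {
  expect_equal(outlier_percent(rep(FALSE, 10)), 0)
  expect_equal(outlier_percent(c(rep(TRUE, 113), rep(FALSE, 887))), 11.3)
})

test_that("percent metrics are scale invariant", {
  set.seed(4)
  x <- stats::rlnorm(50, log(2e-3), 0.2)
  th <- 2e-3
  for (c_ in c(1e-3, 1, 250)) {
    expect_equal(cv_percent(c_ * x), cv_percent(x))
    expect_equal(mean_error_percent(c_ * x, c_ * th),
                 mean_error_percent(x, th))
    expect_equal(unlist(bland_altman(c_ * x, c_ * th)),
                 unlist(bland_altman(x, th)))
  }
})

test_that("ANOVA F and p agree with a label-permutation brute force", {
  set.seed(8)
  groups <- list(m1 = c(1.1, 1.9, 3.2, 2.4, 1.7),
                 m2 = c(2.0, 3.1, 2.6, 3.9, 3.3),
                 m3 = c(1.4, 2.2, 1.8, 2.9, 2.1))
  cmp <- compare_methods(groups)
  # brute-force reference: permutation distribution of the F statistic
  vals <- unlist(groups)
  labs <- rep(names(groups), each = 5)
  f_of <- function(lab) {
    d <- data.frame(value = vals, method = factor(lab))
    summary(stats::aov(value ~ method, d))[[1]]["method", "F value"]
  }
  n_perm <- 2000
  f_perm <- replicate(n_perm, f_of(sample(labs)))
  p_perm <- (1 + sum(f_perm >= cmp$f_statistic)) / (1 + n_perm)
  expect_lt(abs(p_perm - cmp$p_value), 0.04)
  expect_equal(nrow(cmp$tukey), 3)
  expect_setequal(cmp$tukey$pair, c("m2-m1", "m3-m1", "m3-m2"))
})

test_that("Tukey flags exactly the pairs that differ", {
  set.seed(2)
  jit <- function(mu) mu + stats::rnorm(6, 0, 0.01)
  cmp <- compare_methods(list(m1 = jit(0), m2 = jit(1), m3 = jit(0)))
  expect_lt(cmp$p_value, 0.05)
  sig <- cmp$tukey$significant
  names(sig) <- cmp$tukey$pair
  expect_true(sig[["m2-m1"]])
  expect_true(sig[["m3-m2"]])
  expect_false(sig[["m3-m1"]])
  # three identical groups: F = 0, p = 1
  same <- compare_methods(list(a = c(1, 2, 3), b = c(1, 2, 3),
                               c = c(1, 2, 3)))
  expect_equal(same$f_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_methods(list(a = c(1, 1), b = c(2, 2))),
               "zero within-group variance")
})

test_that("metrics table excludes outliers and accounts for every fit", {
  ens <- make_ensemble("tumor", 40, 60, seed = 13)
  fits <- fit_ensemble(ens, methods = "three_parameter")
  met <- metrics_table(fits, list(tumor = tumor_truth))
  expect_equal(nrow(met), 3)  # one row per parameter
  row <- met[met$parameter == "D", ]
  n_out <- sum(fits$outlier)
  expect_equal(row$n_used + n_out, nrow(fits))
  expect_equal(row$outlier_percent, 100 * n_out / nrow(fits))
  expect_equal(row$cv_percent,
               cv_percent(fits$D[!fits$outlier]))
  # including outliers must visibly change the accounting, never silently
  met_all <- metrics_table(fits, list(tumor = tumor_truth),
                           include_outliers = TRUE)
  expect_gt(met_all$n_used[met_all$parameter == "D"], row$n_used)
})
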