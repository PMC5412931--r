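test_that("high-b segment fit equals the closed-form log-linear solution", {
  gm <- ivim_signal(gm_truth, sch11)
  seg <- fit_high_b_segment(gm, 200)
  hi <- sch11$b_values > 200
  oracle <- ols_log_segment(sch11$b_values[hi], gm$values[hi])
  expect_equal(seg$D, oracle$D, tolerance = 1e-12)
  expect_equal(seg$S_int, oracle$S_int, tolerance = 1e-12)
  # gray matter: perfusion is negligible beyond b = 200, so truth is recovered
  expect_lt(abs(seg$D - gm_truth$D) / gm_truth$D, 0.001)
  expect_lt(abs(seg$S_int - (1 - gm_truth$f)) / (1 - gm_truth$f), 0.001)
  # a true mono-exponential is reproduced to solver precision
  seg0 <- fit_high_b_segment(mono_exp_signal(1e-3, 1, sch11), 200)
  expect_equal(seg0$D, 1e-3, tolerance = 1e-10)
  expect_equal(seg0$S_int, 1, tolerance = 1e-10)
})

test_that("segment fit drops non-positive signals and errors when starved", {
  gm <- ivim_signal(gm_truth, sch11)
  vals <- gm$values
  vals[sch11$b_values == 500] <- -0.01  # noise-corrupted sample
  seg <- fit_high_b_segment(signal_curve(sch11, vals), 200)
  expect_equal(seg$n_dropped, 1L)
  expect_equal(seg$n_used, 2L)
  vals[sch11$b_values == 300] <- 0
  expect_error(fit_high_b_segment(signal_curve(sch11, vals), 200),
               "fewer than 2 positive")
  short <- acquisition_scheme(c(0, 100, 250))
  expect_error(fit_high_b_segment(signal_curve(short, c(1, 0.9, 0.8)), 200),
               "fewer than 2 b-values above")
})

test_that("noiseless gray matter is recovered by all three cascades", {
  gm <- ivim_signal(gm_truth, sch11)
  truth <- c(D = gm_truth$D, D_star = gm_truth$D_star, f = gm_truth$f)
  for (m in c("one_parameter", "two_parameter", "three_parameter")) {
    fit <- fit_ivim(gm, method_spec(m))
    expect_false(fit$outlier)
    rel <- abs(fit$estimate - truth) / truth
    expect_true(all(rel < 0.005), info = m)
  }
})

test_that("noiseless tumor: simultaneous fit exact; constrained fits carry the
           perfusion contamination of the high-b segment", {
  tum <- ivim_signal(tumor_truth, sch11)
  truth <- c(D = tumor_truth$D, D_star = tumor_truth$D_star,
             f = tumor_truth$f)
  f3 <- fit_three_parameter(tum)
  expect_true(all(abs(f3$estimate - truth) / truth < 0.005))
  # constrained cascades: D comes from the contaminated segment; the correct
  # reference is therefore the segment oracle, not the generator truth
  hi <- sch11$b_values > 200
  oracle <- ols_log_segment(sch11$b_values[hi], tum$values[hi])
  f1 <- fit_one_parameter(tum)
  f2 <- fit_two_parameter(tum)
  expect_equal(f1$estimate[["D"]], oracle$D, tolerance = 1e-12)
  expect_equal(f1$estimate[["f"]], 1 - oracle$S_int, tolerance = 1e-12)
  # with D*/D only ~4.4, the b > 200 segment still holds ~2% perfusion signal,
  # biasing the constrained cascade even without noise
  expect_gt(abs(f1$estimate[["f"]] - truth[["f"]]) / truth[["f"]], 0.1)
  # the D* estimate is the conditional optimum given the fixed (D, f):
  # cross-check with an independent minimizer over D* alone
  ref <- nlminb_ivim(tum,
                     c(f1$estimate[["D"]], 1e-2, f1$estimate[["f"]]),
                     lower = c(f1$estimate[["D"]], 1e-4, f1$estimate[["f"]]),
                     upper = c(f1$estimate[["D"]], 0.5, f1$estimate[["f"]]))
  expect_equal(f1$estimate[["D_star"]], ref$par[2], tolerance = 1e-5)
  expect_equal(f2$estimate[["D"]], f1$estimate[["D"]])  # shared segment D
})

test_that("simultaneous fit agrees with an independent minimizer", {
  set.seed(11)
  cur <- add_noise(ivim_signal(gm_truth, sch11), noise_spec(50))
  fit <- fit_three_parameter(cur)
  expect_false(fit$outlier)
  ref <- nlminb_ivim(cur, c(1e-3, 1e-2, 0.1),
                     lower = c(1e-5, 1e-4, 0), upper = c(5e-3, 0.5, 1))
  expect_equal(unname(fit$estimate), unname(ref$par), tolerance = 1e-4)
  expect_equal(fit$rss, ref$objective, tolerance = 1e-6)
})

test_that("fitting is deterministic and fixed parameters are bit-identical", {
  set.seed(7)
  cur <- add_noise(ivim_signal(tumor_truth, sch11), noise_spec(40))
  a <- fit_two_parameter(cur)
  b <- fit_two_parameter(cur)
  expect_identical(a, b)
  seg <- fit_high_b_segment(cur, 200)
  expect_identical(a$estimate[["D"]], seg$D)
  expect_identical(fit_one_parameter(cur)$estimate[["D"]], seg$D)
  expect_true(is.na(a$stderr[["D"]]))
})

test_that("degenerate inputs are flagged as outliers", {
  # no decay at all: the Jacobian cannot be conditioned
  flat <- fit_three_parameter(signal_curve(sch11, rep(1, 11)))
  expect_true(flat$outlier)
  # zero perfusion amplitude makes D* unidentifiable in the one-parameter fit
  mono <- fit_one_parameter(mono_exp_signal(1e-3, 1, sch11))
  expect_identical(mono$estimate[["f"]], 0)
  expect_true(mono$outlier)
})

test_that("outlier rule: rank deficiency, condition number, bounds", {
  jac_good <- ivim_jacobian(sch11$b_values, 8.32e-4, 2.68e-2, 0.115,
                            c("D", "D_star", "f"))
  expect_false(detect_outlier(jac_good, converged = TRUE, at_bound = FALSE))
  jac_bad <- jac_good
  jac_bad[, 2] <- 0  # a parameter with no effect on the model
  expect_true(detect_outlier(jac_bad, converged = TRUE, at_bound = FALSE))
  expect_true(detect_outlier(jac_good, converged = FALSE, at_bound = FALSE))
  expect_true(detect_outlier(jac_good, converged = TRUE, at_bound = TRUE))
  # threshold is a knob
  expect_true(detect_outlier(jac_good, TRUE, FALSE, cond_threshold = 1))
})

test_that("estimated D* scatter orders with method constraint (tumor model)", {
  ens <- make_ensemble("tumor", 40, 500, seed = 42)
  fits <- fit_ensemble(ens)
  sds <- vapply(split(fits, fits$method), function(s)
    stats::sd(s$D_star[!s$outlier]), 0)
  expect_lte(sds[["one_parameter"]], sds[["two_parameter"]])
  expect_lte(sds[["two_parameter"]], sds[["three_parameter"]])
})

test_that("batch fitting emits the documented columnar schema", {
  ens <- make_ensemble("gm", 40, 4, seed = 5)
  fits <- fit_ensemble(ens)
  expect_named(fits, c("model", "snr", "iteration", "method", "D", "D_star",
                       "f", "stderr_D", "stderr_D_star", "stderr_f", "rss",
                       "converged", "outlier"))
  expect_equal(nrow(fits), 4 * 3)
  expect_setequal(unique(fits$method),
                  c("one_parameter", "two_parameter", "three_parameter"))
})
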