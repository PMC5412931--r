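test_that("bi-exponential forward model matches direct evaluation", {
  # hand-evaluated values of f*exp(-b D*) + (1-f)*exp(-b D)
  gm <- ivim_signal(gm_truth, sch11)
  expect_identical(gm$values[1], 1)
  expect_equal(gm$values[11],
               0.115 * exp(-1000 * 2.68e-2) + 0.885 * exp(-1000 * 8.32e-4),
               tolerance = 1e-12)
  tum <- ivim_signal(tumor_truth, sch11)
  expect_equal(tum$values[11],
               0.0953 * exp(-1000 * 7.23e-3) + 0.9047 * exp(-1000 * 1.63e-3),
               tolerance = 1e-12)
  # absolute scale check against frozen high-precision values
  expect_equal(gm$values[11], 0.38513258, tolerance = 1e-7)
  expect_equal(tum$values[11], 0.17732653, tolerance = 1e-7)
})

test_that("mono-exponential model and its degeneracy with f = 0", {
  m <- mono_exp_signal(1e-3, 1, sch11)
  expect_identical(m$values[1], 1)
  expect_equal(m$values[11], exp(-1), tolerance = 1e-12)
  m2 <- mono_exp_signal(8.32e-4, 0.885, sch11)
  expect_equal(m2$values[sch11$b_values == 500], 0.885 * exp(-0.416),
               tolerance = 1e-12)
  # f = 0 collapses the bi-exponential to the mono-exponential at every b
  for (D in c(5e-4, 1e-3, 2.5e-3)) {
    bi <- ivim_signal(ivim_params(D, 1e-2, 0), sch11)
    expect_equal(bi$values, mono_exp_signal(D, 1, sch11)$values,
                 tolerance = 1e-14)
  }
})

test_that("noiseless curves decrease monotonically in b and in each parameter", {
  grid <- expand.grid(D = c(5e-4, 1.63e-3), D_star = c(7e-3, 3e-2),
                      f = c(0.05, 0.115, 0.3))
  for (k in seq_len(nrow(grid))) {
    p <- ivim_params(grid$D[k], grid$D_star[k], grid$f[k])
    v <- ivim_signal(p, sch11)$values
    expect_true(all(diff(v) < 0))
    # larger D, D*, f each depress the signal at every b > 0
    for (fld in c("D", "D_star", "f")) {
      p2 <- p
      p2[[fld]] <- p[[fld]] * 1.2
      v2 <- ivim_signal(ivim_params(p2$D, p2$D_star, p2$f), sch11)$values
      expect_true(all(v2[-1] < v[-1]))
    }
  }
})

test_that("perfusion fraction from intercept, with clamping flag", {
  expect_equal(as.numeric(perfusion_fraction_from_intercept(1, 1)), 0)
  expect_equal(as.numeric(perfusion_fraction_from_intercept(1, 0.885)), 0.115)
  expect_equal(as.numeric(perfusion_fraction_from_intercept(1, 0.9047)),
               0.0953)
  expect_false(attr(perfusion_fraction_from_intercept(1, 0.9), "clamped"))
  over <- perfusion_fraction_from_intercept(1, 1.04)  # noisy over-shoot
  expect_true(attr(over, "clamped"))
  expect_identical(as.numeric(over), 0)
  under <- perfusion_fraction_from_intercept(1, -0.1)
  expect_true(attr(under, "clamped"))
  expect_identical(as.numeric(under), 1)
  # noiseless self-consistency: extrapolating the tissue compartment to b = 0
  # leaves exactly the perfusion fraction
  for (f in c(0.02, 0.0953, 0.115, 0.4))
    expect_equal(as.numeric(perfusion_fraction_from_intercept(1, 1 - f)), f)
})

test_that("validation errors name the violated invariant", {
  expect_error(ivim_params(-1e-3, 1e-2, 0.1), "D must be > 0")
  expect_error(ivim_params(1e-3, 0, 0.1), "D_star must be > 0")
  expect_error(ivim_params(1e-3, 1e-2, 1.2), "f must lie in")
  expect_error(acquisition_scheme(c(10, 20)), "first b-value must be 0")
  expect_error(acquisition_scheme(c(0, 20, 20)), "strictly increasing")
  expect_error(acquisition_scheme(c(0, -5, 10)), ">= 0")
  expect_error(mono_exp_signal(0, 1, sch11), "D must be > 0")
  expect_error(mono_exp_signal(1e-3, -1, sch11), "intercept must be > 0")
  expect_error(perfusion_fraction_from_intercept(0, 1), "S0 must be > 0")
  expect_error(signal_curve(sch11, 1:3), "one entry per b-value")
  # D* <= D is constructible but reported as outside the bi-exponential regime
  p <- ivim_params(2e-3, 1e-3, 0.1)
  expect_false(is_biexponential(p))
  expect_true(is_biexponential(gm_truth))
})
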