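test_that("an exact two-segment trace is recovered to the sampling grid", {
  tr <- piecewise_trace(brk = 600, slope1 = 20e-9, slope2 = 200e-9)
  ft <- estimate_tau(tr, n_boot = 0)
  expect_true(ft$breakpoint_found)
  expect_equal(ft$tau, 600, tolerance = 1 / 600)
  expect_equal(ft$slope1, 20e-9, tolerance = 1e-6)
  expect_equal(ft$slope2, 200e-9, tolerance = 1e-6)
})

test_that("a closed-form induction trace yields tau within 5%", {
  tr <- closedform_trace(tau = 432)
  ft <- estimate_tau(tr, n_boot = 0)
  expect_equal(ft$tau, 432, tolerance = 0.05)
})

test_that("noisy closed-form traces give median tau within 10%", {
  base <- closedform_trace(tau = 432)
  taus <- vapply(1:20, function(s) {
    noisy <- add_sensor_noise(base, noise_model(sigma = 0.2e-6, seed = s))
    estimate_tau(noisy, n_boot = 0)$tau
  }, numeric(1))
  expect_lt(abs(median(taus) / 432 - 1), 0.10)
})

test_that("tau estimation is equivariant under time shift and rescaling", {
  base <- closedform_trace(tau = 432)
  noisy <- add_sensor_noise(base, noise_model(sigma = 0.1e-6, seed = 11))
  ft0 <- estimate_tau(noisy, n_boot = 0)
  shifted <- o2_trace(noisy$times + 750, noisy$o2_consumed * 3.7,
                      injection_time = 750, noisy = TRUE)
  ft1 <- estimate_tau(shifted, n_boot = 0)
  expect_equal(ft1$tau, ft0$tau, tolerance = 1e-8)
  expect_equal(ft1$slope1, 3.7 * ft0$slope1, tolerance = 1e-8)
})

test_that("a straight trace reports no induction breakpoint", {
  t <- seq(0, 2000, by = 5)
  y <- 4e-7 * t
  noisy <- add_sensor_noise(o2_trace(t, y, 0), noise_model(seed = 3))
  ft <- estimate_tau(noisy, n_boot = 0)
  expect_false(ft$breakpoint_found)
  expect_true(is.na(ft$tau))
})

test_that("short records raise the insufficient-data signal", {
  tr <- o2_trace(seq(0, 50, by = 5), seq(0, 50, by = 5) * 1e-9, 0)
  expect_error(estimate_tau(tr), class = "autoxkin_insufficient_data")
})

test_that("the bootstrap SD is reproducible under a fixed seed", {
  base <- closedform_trace(tau = 432)
  noisy <- add_sensor_noise(base, noise_model(sigma = 0.2e-6, seed = 5))
  f1 <- estimate_tau(noisy, n_boot = 50, seed = 99)
  f2 <- estimate_tau(noisy, n_boot = 50, seed = 99)
  expect_identical(f1$tau_sd, f2$tau_sd)
  expect_gt(f1$tau_sd, 0)
})

test_that("a missing injection time warns and measures from t = 0", {
  tr <- piecewise_trace()
  tr$injection_time <- NA_real_
  expect_warning(ft <- estimate_tau(tr, n_boot = 0), "injection")
  expect_equal(ft$tau, 600, tolerance = 0.01)
})
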