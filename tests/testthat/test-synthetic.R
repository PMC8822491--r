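pmhc_system <- function() {
  liposome_system(pH_label = 6, R_i = 2.3e-9,
                  antioxidants = list(antioxidant("PMHC", 1e-6, 7.9e3)))
}

test_that("zero noise reproduces the deterministic protocol exactly", {
  sys <- pmhc_system()
  tr0 <- generate_trace(sys, noise = noise_model(sigma = 0, seed = 1),
                        t_end = 4000)
  tr1 <- generate_trace(sys, noise = noise_model(sigma = 0, seed = 2),
                        t_end = 4000)
  expect_identical(tr0$o2_consumed, tr1$o2_consumed)
  expect_false(tr0$noisy)
  expect_true(all(diff(tr0$o2_consumed) >= -1e-15))
})

test_that("a fixed seed gives bit-identical noisy traces", {
  sys <- pmhc_system()
  a <- generate_trace(sys, noise = noise_model(seed = 42), t_end = 4000)
  b <- generate_trace(sys, noise = noise_model(seed = 42), t_end = 4000)
  expect_identical(a$o2_consumed, b$o2_consumed)
  expect_identical(a$times, b$times)
  c <- generate_trace(sys, noise = noise_model(seed = 43), t_end = 4000)
  expect_false(identical(a$o2_consumed, c$o2_consumed))
})

test_that("injection happens at 10% oxygen depletion", {
  sys <- pmhc_system()
  tr <- generate_trace(sys, noise = noise_model(sigma = 0, seed = 1),
                       t_end = 4000)
  at_inj <- approx(tr$times, tr$o2_consumed, xout = tr$injection_time)$y
  step <- max(abs(diff(tr$o2_consumed[tr$times <= tr$injection_time])))
  expect_lt(abs(at_inj - 0.1 * sys$O2_0), step + 1e-9)
})

test_that("a horizon before the injection time fails loudly", {
  expect_error(
    generate_trace(pmhc_system(), noise = noise_model(seed = 1), t_end = 100),
    class = "autoxkin_generation_failure")
})

test_that("sensor noise does not bias the inhibited rate", {
  sys <- pmhc_system()
  base <- generate_trace(sys, noise = noise_model(sigma = 0, seed = 1),
                         t_end = 4000)
  tau <- estimate_tau(base, n_boot = 0)$tau
  r0 <- estimate_phase_rates(base, tau)$R_inh
  rs <- vapply(1:50, function(s) {
    noisy <- add_sensor_noise(base, noise_model(sigma = 0.2e-6, seed = s))
    estimate_phase_rates(noisy, tau)$R_inh
  }, numeric(1))
  expect_lt(abs(mean(rs) / r0 - 1), 0.02)
})

test_that("the benchmark design counts media x pH x settings", {
  s <- generate_benchmark_suite(seed = 5, media = "micelle", pHs = c(4, 7))
  expect_length(s$traces, 2 * 5)
  expect_identical(nrow(s$truth), 10L)
  expect_setequal(unique(s$truth$setting),
                  c("uninhibited", "PMHC", "RSV", "weak", "PMHC/RSV"))
  # reference-calibrated truth: PMHC rows are the n = 2 anchor
  pm <- s$truth[s$truth$setting == "PMHC", ]
  expect_equal(pm$n_true, rep(2, nrow(pm)))
})
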