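test_that("phase rates are exact on a two-segment trace", {
  tr <- piecewise_trace(brk = 600, slope1 = 20e-9, slope2 = 200e-9)
  r <- estimate_phase_rates(tr, tau = 600)
  expect_equal(r$R_inh, 20e-9, tolerance = 1e-9)
  expect_equal(r$R_ox2, 200e-9, tolerance = 1e-9)
  # retarded trace: whole-record slope, no post-induction rate
  r2 <- estimate_phase_rates(piecewise_trace(brk = 1500), tau = NULL)
  expect_equal(r2$R_inh, 20e-9, tolerance = 1e-9)
  expect_true(is.na(r2$R_ox2))
})

test_that("on a convex induction curve R_inh lies between the edge slopes", {
  tau <- 800; k_inh <- 5e3; k_p <- 36; LH <- 2.74e-3
  t <- seq(0, 0.9 * tau, by = 2)
  tr <- o2_trace(t, closed_form_uptake(t, tau, k_inh, k_p, LH), 0)
  r <- estimate_phase_rates(tr, tau = tau)
  inst <- function(tt) k_p * LH / k_inh / tau / (1 - tt / tau)
  expect_gt(r$R_inh, inst(0.15 * tau))
  expect_lt(r$R_inh, inst(0.85 * tau))
})

test_that("initiation-rate calibration follows the induction-period relation", {
  expect_equal(compute_Ri(432, 2, 1e-6), 4.6296e-9, tolerance = 1e-4)
  expect_equal(compute_Ri(876, 2, 1e-6), 2.2831e-9, tolerance = 1e-4)
  expect_equal(compute_Ri(600, 1, 6e-7), 1.0e-9)
  expect_error(compute_Ri(0, 2, 1e-6), class = "autoxkin_division_error")
})

test_that("stoichiometric factors reproduce printed-row arithmetic", {
  expect_equal(compute_n(2448, 2.283e-9, 1e-6), 5.59, tolerance = 1e-3)
  expect_equal(compute_n(888, 3.876e-9, 1e-6), 3.44, tolerance = 1e-2)
  expect_equal(compute_n(0, 5e-9, 1e-6), 0)
  expect_error(compute_n(100, 1e-9, 0), class = "autoxkin_division_error")
})

test_that("Eq-8 arithmetic round-trips exactly", {
  set.seed(42)
  for (i in 1:25) {
    tau <- runif(1, 100, 5000)
    conc <- 10^runif(1, -7, -5)
    expect_equal(compute_n(tau, compute_Ri(tau, 2, conc), conc), 2)
  }
})

test_that("k_inh inversion is exact on noiseless closed-form traces", {
  set.seed(7)
  for (i in 1:10) {
    tau <- runif(1, 300, 3000)
    k_inh <- 10^runif(1, 3, 5)
    t <- seq(0, 0.9 * tau, length.out = 300)
    tr <- o2_trace(t, closed_form_uptake(t, tau, k_inh, 36, 2.74e-3), 0)
    expect_equal(estimate_kinh(tr, tau, 36, 2.74e-3), k_inh,
                 tolerance = 1e-6)
  }
})

test_that("k_inh estimation signals degenerate inputs", {
  t <- seq(0, 900, by = 5)
  tr <- o2_trace(t, rev(seq_along(t)) * 1e-9 - 181e-9, 0, noisy = TRUE)
  expect_error(estimate_kinh(tr, 1000, 36, 2.74e-3),
               class = "autoxkin_fit_failure")
  short <- o2_trace(c(0, 400, 800), c(0, 1e-6, 2e-6), 0)
  expect_error(estimate_kinh(short, 1000, 36, 2.74e-3),
               class = "autoxkin_insufficient_data")
})

test_that("capacity correction scales the apparent constant by n/2", {
  expect_equal(correct_kinh(3.3e3, 5.6), 9.24e3)
  expect_equal(correct_kinh(7.7e2, 2.0), 7.7e2)
  expect_equal(correct_kinh(1.2e3, 4.9), 2.94e3)
})

test_that("kinetic chain lengths match printed rows", {
  expect_equal(compute_nu(35e-9, compute_Ri(7.2 * 60, 2, 1e-6)), 7.56,
               tolerance = 1e-3)
  expect_equal(compute_nu(103e-9, compute_Ri(7.2 * 60, 2, 1e-6)), 22.2,
               tolerance = 1e-2)
  expect_equal(compute_nu(0, 4.6e-9), 0)
  expect_error(compute_nu(1e-8, 0), class = "autoxkin_division_error")
})

test_that("co-antioxidant stoichiometry follows the mixture relation", {
  expect_equal(synergy_n(3864, 876, 2.283e-9, 1e-6), 6.82, tolerance = 1e-2)
  expect_equal(synergy_n(2448, 516, 3.876e-9, 1e-6), 7.49, tolerance = 1e-2)
  expect_equal(synergy_n(876, 876, 2.283e-9, 1e-6), 0)
  expect_warning(out <- synergy_n(500, 876, 2.283e-9, 1e-6), "negative")
  expect_lt(out, 0)
})

test_that("classification applies the slow-down thresholds", {
  expect_identical(classify(15.8, TRUE), "inhibition")
  expect_identical(classify(1.4, FALSE), "retardation")
  expect_identical(classify(1.0, FALSE), "none")
  expect_identical(classify(2.5, TRUE), "retardation")
  expect_identical(classify(2.5, TRUE, inhibition_min = 2), "inhibition")
  expect_error(classify(NA_real_, TRUE), class = "autoxkin_cannot_classify")
})

test_that("classification is monotone in the inhibition constant", {
  # simulated series in a sharp regime; a stronger inhibitor must never be
  # demoted relative to a weaker one at otherwise fixed conditions
  p <- reaction_parameters(k_p = 41, two_kt = 3e5)
  R_ox <- steady_state_rox(liposome_system(R_i = 2.3e-9), p)
  rank <- c(none = 0, retardation = 1, inhibition = 2)
  got <- vapply(c(1e4, 1e5, 1e6, 1e7), function(k) {
    sys <- liposome_system(R_i = 2.3e-9,
                           antioxidants = list(antioxidant("A", 1e-6, k)))
    tr <- simulate_uptake(sys, p, t_end = 1300, dt_out = 5)
    ft <- estimate_tau(tr, n_boot = 0)
    slow <- R_ox / estimate_phase_rates(tr, ft$tau)$R_inh
    rank[[classify(slow, ft$breakpoint_found)]]
  }, numeric(1))
  expect_true(all(diff(got) >= 0))
  expect_identical(got[[length(got)]], 2)
})
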