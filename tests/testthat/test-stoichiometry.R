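# Effective stoichiometry of simulated antioxidants, in a sharp-induction
# regime (strong inhibitor, fast peroxyl termination) where the breakpoint
# is well defined: k_inh = 1e6, 2k_t = 3e5; phenoxyl coupling at k_dim = 2e3
# against cross-termination at 1e6 gives a partial coupling yield, so each
# realised dimer generation adds a fraction of a radical per parent.

stoich_system <- function(depth = NULL, dimer_k = 1e6) {
  ao <- if (is.null(depth)) {
    antioxidant("X", 1e-6, 1e6)
  } else {
    antioxidant("X", 1e-6, 1e6, dimerizes = TRUE, dimer_k_inh = dimer_k,
                cascade_depth = depth)
  }
  liposome_system(R_i = 2.3e-9, antioxidants = list(ao))
}
stoich_params <- reaction_parameters(k_p = 41, two_kt = 3e5,
                                     k_rad_cross = 1e6, k_dim = 2e3)

test_that("a non-dimerizing phenol traps two radicals", {
  n <- effective_stoichiometry(stoich_system(),
                               reaction_parameters(k_p = 41, two_kt = 3e5))
  expect_equal(n, 2, tolerance = 0.05)
})

test_that("trapping-competent dimers raise n above 2; inert coupling does not", {
  n1 <- effective_stoichiometry(stoich_system(depth = 1), stoich_params)
  expect_gt(n1, 2.15)
  n_inert <- effective_stoichiometry(stoich_system(depth = 0, dimer_k = 0),
                                     stoich_params)
  expect_lte(n_inert, 2.1)
})

test_that("n is non-decreasing in the cascade depth", {
  ns <- vapply(0:3, function(d) {
    effective_stoichiometry(stoich_system(depth = d), stoich_params)
  }, numeric(1))
  expect_true(all(diff(ns) > -0.02 * ns[-length(ns)]))
  expect_gt(ns[4], ns[1])
})

test_that("an undetectable induction raises the no-induction signal", {
  sys <- liposome_system(R_i = 2.3e-9,
                         antioxidants = list(antioxidant("W", 1e-6, 30)))
  expect_error(
    effective_stoichiometry(sys, reaction_parameters(k_p = 41, two_kt = 3e5),
                            t_end = 2000),
    class = "autoxkin_no_induction")
})
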