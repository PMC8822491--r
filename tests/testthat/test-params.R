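test_that("parameter and system constructors enforce their invariants", {
  expect_error(reaction_parameters(k_p = -1), "rate constants")
  expect_warning(reaction_parameters(k_p = 36, k_O2 = 1e3),
                 "fast-oxygenation")
  expect_error(antioxidant("A", 1e-6, 0), "k_inh")
  expect_error(antioxidant("A", -1e-6, 1e4), "conc0")
  expect_error(antioxidant("A", 1e-6, 1e4, cascade_depth = 2),
               "cascade_depth")
  expect_silent(antioxidant("A", 1e-6, 1e4, dimerizes = TRUE,
                            cascade_depth = 2))
  expect_error(experiment_system(LH0 = 0), "LH0")
  expect_error(experiment_system(O2_0 = 0, O2_clamped = FALSE), "O2_0")
  expect_error(
    experiment_system(antioxidants = list(antioxidant("A", 1e-6, 1e4),
                                          antioxidant("A", 1e-6, 2e4))),
    "duplicate")
})

test_that("medium defaults carry the right propagation constants", {
  expect_equal(kp_for_medium("micelle"), 36)
  expect_equal(kp_for_medium("liposome"), 41)
  expect_equal(kp_for_medium(liposome_system()), 41)
  expect_equal(micelle_system()$R_i, 4.6e-9)
  expect_equal(liposome_system()$R_i, 2.3e-9)
  expect_equal(micelle_system()$LH0, 2.74e-3)
})
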