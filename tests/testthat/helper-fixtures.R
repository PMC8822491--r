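# Shared fixture builders (all fixtures are generated in code).

# Exact two-segment piecewise-linear trace: slope1 until `brk`, slope2 after.
piecewise_trace <- function(brk = 600, slope1 = 20e-9, slope2 = 200e-9,
                            t_end = 1500, dt = 5, injection = 0) {
  t <- seq(0, t_end, by = dt)
  y <- ifelse(t <= brk, slope1 * t, slope1 * brk + slope2 * (t - brk))
  o2_trace(t + injection, y, injection_time = injection)
}

# Induction phase following the integrated inhibited-rate law, continued
# with the uninhibited slope from the tangent point (where the inhibited
# rate reaches R_ox, i.e. where inhibition has effectively ended).
closedform_trace <- function(tau = 432, k_inh = 1.4e4, k_p = 36,
                             LH = 2.74e-3, R_ox = 4.4e-7, t_end = 1000,
                             dt = 2) {
  t_star <- tau - k_p * LH / (k_inh * R_ox)
  t <- seq(0, t_end, by = dt)
  y_star <- closed_form_uptake(t_star, tau, k_inh, k_p, LH)
  y <- ifelse(t < t_star,
              closed_form_uptake(pmin(t, t_star), tau, k_inh, k_p, LH),
              y_star + R_ox * (t - t_star))
  o2_trace(t, y, injection_time = 0)
}

# Strong-inhibitor regime in which the Eq-8 identity assumptions hold:
# strong suppression (k_inh c >> sqrt(R_i 2k_t)) and a radical inventory
# small next to the antioxidant loading (sqrt(R_i/2k_t) << c).
eq8_regime <- function(medium = "liposome") {
  R_i <- if (medium == "micelle") 4.63e-9 else 2.3e-9
  list(system = experiment_system(medium = medium, R_i = R_i,
                                  antioxidants = list(
                                    antioxidant("A", 1e-6, 1e7))),
       params = reaction_parameters(k_p = kp_for_medium(medium),
                                    two_kt = 3e5))
}
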