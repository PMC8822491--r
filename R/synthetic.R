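#' Time at which the uninhibited system reaches a given uptake
#'
#' Uses the closed-form transient of the uninhibited chain
#' (uptake = R_ox t_c log cosh(t/t_c), with t_c = 1/sqrt(R_i 2k_t)), which
#' covers both the quadratic radical build-up and the linear steady phase.
#' @noRd
depletion_time_estimate <- function(system, params, target) {
  rox <- steady_state_rox(system, params)
  tc <- 1 / sqrt(system$R_i * params$two_kt)
  logcosh <- function(x) ifelse(x > 20, x + log1p(exp(-2 * x)) - log(2),
                                log(cosh(x)))
  f <- function(t) rox * tc * logcosh(t / tc) - target
  hi <- target / rox + 2 * tc
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(0, hi), tol = 1e-3)$root
}

#' Sensor noise model for synthetic Clark-electrode traces
#'
#' @param sigma Additive Gaussian noise SD on each O2 reading (M). The
#'   default 0.2 uM resembles the smoothness of published electrode traces.
#' @param drift Linear baseline drift (M s^-1).
#' @param sampling_dt Interval between readings (s).
#' @param seed Integer seed; required by [generate_trace()] so fixtures are
#'   bit-reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.2e-6, drift = 0, sampling_dt = 5,
                        seed = NULL) {
  stopifnot(sigma >= 0, sampling_dt > 0)
  structure(list(sigma = sigma, drift = drift, sampling_dt = sampling_dt,
                 seed = seed), class = "noise_model")
}

#' Simulate the injection protocol and return the noiseless sampled trace
#'
#' Runs the uninhibited system until 10% of the initial dissolved O2 has been
#' consumed, adds the antioxidant roster at that instant, and continues.
#' @noRd
generate_noiseless <- function(system, params, sampling_dt, t_end,
                               depletion_fraction = 0.1) {
  target <- depletion_fraction * system$O2_0
  base <- system
  base$antioxidants <- list()

  rox <- steady_state_rox(system, params)
  if (!is.finite(rox) || rox <= 0) {
    stop_autoxkin("autoxkin_generation_failure",
                  "uninhibited uptake rate is zero; 10% depletion never reached")
  }
  horizon <- 2 * depletion_time_estimate(system, params, target)
  out1 <- NULL
  for (try in 1:5) {
    dense <- seq(0, horizon, length.out = 600L)
    out1 <- integrate_network(base, params, dense)
    up1 <- out1[, "dO2"]
    if (max(up1) >= target) break
    horizon <- horizon * 2
  }
  if (max(up1) < target) {
    stop_autoxkin("autoxkin_generation_failure",
                  "10% O2 depletion not reached within the search horizon")
  }
  k <- which(up1 >= target)[1L]
  t_inj <- stats::approx(up1[(k - 1L):k], dense[(k - 1L):k], xout = target)$y

  if (t_end <= t_inj) {
    stop_autoxkin("autoxkin_generation_failure",
                  sprintf("t_end (%.4g s) is before the injection time (%.4g s)",
                          t_end, t_inj))
  }

  grid <- seq(0, t_end, by = sampling_dt)
  pre <- grid[grid <= t_inj]
  # exact states on the pre-injection sample times plus the injection instant
  out_pre <- integrate_network(base, params, unique(c(pre, t_inj)))
  state_inj <- out_pre[nrow(out_pre), -1L]

  plan <- species_plan(system, params)
  n <- plan$n_units
  y0 <- numeric(3L + 2L * n)
  y0[1L] <- state_inj[["LH"]]
  y0[2L] <- state_inj[["LOO"]]
  if (n) y0[2L + seq_len(n)] <- plan$conc0
  y0[3L + 2L * n] <- state_inj[["dO2"]]
  # cumulative ledgers continue across the injection
  y0 <- c(y0[seq_len(2L + 2L * n)], state_inj[["dO2"]],
          state_inj[["terminated"]], state_inj[["LOOH"]])

  post <- grid[grid > t_inj]
  out_post <- integrate_network(system, params,
                                unique(c(0, post - t_inj)), y0 = y0)
  up_post <- out_post[match(round(post - t_inj, 9),
                            round(out_post[, 1L], 9)), "dO2"]
  up_pre <- out_pre[match(round(pre, 9), round(out_pre[, 1L], 9)), "dO2"]

  o2_trace(times = grid, o2_consumed = c(up_pre, up_post),
           injection_time = t_inj,
           metadata = list(medium = system$medium, pH = system$pH_label,
                           R_i = system$R_i, LH0 = system$LH0,
                           k_p = params$k_p,
                           O2_0 = system$O2_0,
                           compounds = roster_frame(system),
                           source = "generate_trace"))
}

#' Generate a synthetic oxygen-uptake trace with the injection protocol
#'
#' Emulates the experimental run: the uninhibited system is simulated until
#' 10% of the dissolved O2 is consumed, the antioxidant roster is injected at
#' that instant (recorded as `injection_time`), the run continues to `t_end`,
#' readings are sampled every `sampling_dt` seconds, and Gaussian sensor
#' noise plus optional linear drift is added. Bit-reproducible for a fixed
#' `noise$seed`.
#'
#' @inheritParams simulate_uptake
#' @param noise A [noise_model()]; its `seed` must be set.
#' @param t_end Total run length (s); must exceed the injection time.
#' @return An [o2_trace()] (`noisy = TRUE` when `sigma > 0` or `drift != 0`).
#' @export
generate_trace <- function(system, params = NULL, noise = noise_model(seed = 1),
                           t_end) {
  stopifnot(inherits(noise, "noise_model"))
  if (is.null(noise$seed)) {
    stop("noise$seed must be set for reproducible generation", call. = FALSE)
  }
  if (is.null(params)) params <- reaction_parameters(kp_for_medium(system))
  base <- generate_noiseless(system, params, noise$sampling_dt, t_end)
  add_sensor_noise(base, noise)
}

#' Add sensor noise and drift to a noiseless trace
#'
#' Exposed so replicate noisy realisations of one mechanistic trajectory can
#' be produced without re-integrating the reaction network.
#'
#' @param trace A noiseless [o2_trace()].
#' @param noise A [noise_model()] with its `seed` set.
#' @return A noisy [o2_trace()].
#' @export
add_sensor_noise <- function(trace, noise) {
  if (noise$sigma == 0 && noise$drift == 0) return(trace)
  eps <- with_seed(noise$seed,
                   stats::rnorm(length(trace$times), 0, noise$sigma))
  md <- trace$metadata
  md$seed <- noise$seed
  md$sigma <- noise$sigma
  md$drift <- noise$drift
  o2_trace(times = trace$times,
           o2_consumed = trace$o2_consumed + eps + noise$drift * trace$times,
           injection_time = trace$injection_time,
           metadata = md, noisy = TRUE)
}

#' Printed-table inhibition constants used as fixture defaults
#'
#' Apparent k_inh values (M^-1 s^-1) reported for 1 uM antioxidant in each
#' medium/pH condition; these are mechanistic inputs for the benchmark
#' generator, never outputs of the pipeline.
#' @noRd
fixture_kinh <- function(medium, pH, compound) {
  tab <- list(
    micelle = list(PMHC = c(`4` = 10.9e3, `6` = 6.7e3, `7` = 18.8e3,
                            `8` = 17.0e3, `10` = 29.2e3),
                   RSV = c(`4` = 1.5e3, `6` = 1.2e3, `7` = 1.5e3,
                           `8` = 2.5e3, `10` = 3.7e3)),
    liposome = list(PMHC = c(`4` = 12.8e3, `6` = 7.9e3, `7` = 14.0e3,
                             `8` = 12.3e3, `10` = 16.1e3),
                    RSV = c(`4` = 4.9e3, `6` = 3.3e3, `7` = 7.1e3,
                            `8` = 5.5e3, `10` = NA)))
  unname(tab[[medium]][[compound]][as.character(pH)])
}

#' Generate the labelled benchmark suite of synthetic traces
#'
#' Mimics the design of the kinetic-table experiments: for each of 2 media
#' (micelle, R_i = 4.6 nM/s; liposome, R_i = 2.3 nM/s) and 5 pH labels
#' (4, 6, 7, 8, 10), five settings are generated - uninhibited, the n = 2
#' reference PMHC, an RSV-like antioxidant whose phenoxyls couple to
#' trapping-competent dimers (cascade depth 4), a weak retarder, and the
#' equimolar PMHC/RSV mixture - giving 50 traces at 1 uM per compound,
#' sigma = 0.2 uM, 5 s sampling. The RSV-like compound at liposomal pH 10 is
#' replaced by a weak, non-coupling phenol (fast alkaline decomposition
#' regime, retardation only). Mixtures carry the mild regeneration constants
#' (k_r = 20 >= 2k_TO = 15 M^-1 s^-1).
#'
#' @param seed Integer master seed; every trace gets a derived sub-seed.
#' @param sigma Noise SD (M).
#' @param sampling_dt Sampling interval (s).
#' @param media,pHs Condition labels to generate.
#' @return List with `traces` (named list of [o2_trace()]) and `truth`, a
#'   data frame holding the generating parameters (`R_i`, `conc`,
#'   `k_inh_input`, `seed`) and the noiseless-pipeline reference values used
#'   by the recovery tests: `tau_true` (s), `R_inh_true` (M/s), `k_inh_app`
#'   (the apparent inhibition constant the estimator reads off the noiseless
#'   trace), the reference-calibrated `R_i_cal` and `n_true`, and for
#'   mixtures `tau_sum_true` and `hyper_true`.
#' @export
generate_benchmark_suite <- function(seed = 20260928, sigma = 0.2e-6,
                                     sampling_dt = 5,
                                     media = c("micelle", "liposome"),
                                     pHs = c(4, 6, 7, 8, 10)) {
  settings <- c("uninhibited", "PMHC", "RSV", "weak", "PMHC/RSV")
  combos <- expand.grid(medium = media, pH = pHs, setting = settings,
                        stringsAsFactors = FALSE)
  sub_seeds <- with_seed(seed, sample.int(2^30, nrow(combos)))

  traces <- list()
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    medium <- combos$medium[i]; pH <- combos$pH[i]; setting <- combos$setting[i]
    R_i <- if (medium == "micelle") 4.6e-9 else 2.3e-9
    params <- reaction_parameters(k_p = kp_for_medium(medium))
    aos <- list()
    if (setting %in% c("PMHC", "PMHC/RSV")) {
      aos <- c(aos, list(antioxidant("PMHC", 1e-6,
                                     fixture_kinh(medium, pH, "PMHC"),
                                     regenerable = TRUE)))
    }
    if (setting %in% c("RSV", "PMHC/RSV")) {
      k <- fixture_kinh(medium, pH, "RSV")
      if (is.na(k)) {
        aos <- c(aos, list(antioxidant("RSV", 1e-6, 400)))
      } else {
        aos <- c(aos, list(antioxidant("RSV", 1e-6, k, dimerizes = TRUE,
                                       dimer_k_inh = k, cascade_depth = 4L)))
        # interface-concentrated phenoxyls: coupling outcompetes the rare
        # phenoxyl-peroxyl encounters in the dispersed pseudo-phase
        params$k_rad_cross <- 1e6
        params$k_dim <- 1e9
      }
    }
    if (setting == "weak") {
      aos <- list(antioxidant("weak", 1e-6, 400))
    }
    if (setting == "PMHC/RSV") {
      params$k_r <- 20   # >= two_k_AO = 15, the mild-regeneration regime
    }
    sys <- experiment_system(medium = medium, pH_label = pH, R_i = R_i,
                             antioxidants = aos)
    cap <- sum(vapply(aos, function(a) {
      (2 + if (a$dimerizes) a$cascade_depth else 0) * a$conc0
    }, numeric(1)))
    t_inj_est <- depletion_time_estimate(sys, params, 0.1 * sys$O2_0)
    t_end <- t_inj_est + max(2.5 * cap / R_i, 3600)

    noiseless <- generate_noiseless(sys, params, sampling_dt, t_end)
    nm <- noise_model(sigma = sigma, sampling_dt = sampling_dt,
                      seed = sub_seeds[i])
    noisy <- add_sensor_noise(noiseless, nm)
    label <- sprintf("%s_pH%s_%s", medium, format(pH),
                     gsub("/", "_", setting))
    traces[[label]] <- noisy

    truth <- data.frame(label = label, medium = medium, pH = pH,
                        setting = setting, R_i = R_i,
                        conc = if (length(aos)) aos[[1L]]$conc0 else NA_real_,
                        k_inh_input = if (setting %in% c("PMHC", "RSV", "weak"))
                          aos[[1L]]$k_inh else NA_real_,
                        seed = sub_seeds[i],
                        tau_true = NA_real_, n_true = NA_real_,
                        R_inh_true = NA_real_, k_inh_app = NA_real_,
                        stringsAsFactors = FALSE)
    if (length(aos)) {
      ft <- estimate_tau(noiseless, n_boot = 0)
      if (ft$breakpoint_found) {
        truth$tau_true <- ft$tau
        truth$R_inh_true <- estimate_phase_rates(noiseless, ft$tau)$R_inh
        if (length(aos) == 1L) {
          truth$k_inh_app <- tryCatch(
            estimate_kinh(noiseless, ft$tau, params$k_p, sys$LH0),
            autoxkin_error = function(e) NA_real_)
        }
      } else {
        truth$R_inh_true <- estimate_phase_rates(noiseless, NULL)$R_inh
      }
    }
    rows[[i]] <- truth
  }
  truth <- do.call(rbind, rows)

  # calibrate stoichiometric truth exactly as the pipeline does: R_i from the
  # noiseless PMHC induction period (n = 2) at the same condition
  truth$R_i_cal <- NA_real_
  truth$n_true <- NA_real_
  truth$tau_sum_true <- NA_real_
  truth$hyper_true <- NA_real_
  for (cd in unique(paste(truth$medium, truth$pH))) {
    sel <- paste(truth$medium, truth$pH) == cd
    ref <- truth[sel & truth$setting == "PMHC", ]
    if (!nrow(ref) || !is.finite(ref$tau_true)) next
    R_i_cal <- compute_Ri(ref$tau_true, 2, ref$conc)
    truth$R_i_cal[sel] <- R_i_cal
    single <- sel & truth$setting %in% c("PMHC", "RSV", "weak") &
      is.finite(truth$tau_true)
    truth$n_true[single] <- compute_n(truth$tau_true[single], R_i_cal,
                                      truth$conc[single])
    mix <- sel & truth$setting == "PMHC/RSV"
    rsv <- truth[sel & truth$setting == "RSV", ]
    if (any(mix) && is.finite(truth$tau_true[mix]) &&
        nrow(rsv) && is.finite(rsv$tau_true)) {
      truth$n_true[mix] <- synergy_n(truth$tau_true[mix], ref$tau_true,
                                     R_i_cal, 1e-6)
      truth$tau_sum_true[mix] <- ref$tau_true + rsv$tau_true
      truth$hyper_true[mix] <- truth$tau_true[mix] / truth$tau_sum_true[mix]
    }
  }
  list(traces = traces, truth = truth)
}

#' Write a benchmark suite to a directory of delimited files
#'
#' Emits one trace file per run (standard trace format) plus a `truth.csv`
#' table of the generating parameters.
#'
#' @param suite Result of [generate_benchmark_suite()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark_suite <- function(suite, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(suite$traces)) {
    write_trace(suite$traces[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  utils::write.csv(suite$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
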