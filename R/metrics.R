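#' Least-squares slope over a time window of a trace
#' @noRd
window_slope <- function(t, y, lo, hi, min_points = 5L) {
  keep <- t >= lo & t <= hi
  if (sum(keep) < min_points) {
    stop_autoxkin("autoxkin_insufficient_data",
                  sprintf("fit window [%.3g, %.3g] s holds %d point(s); need >= %d",
                          lo, hi, sum(keep), min_points))
  }
  unname(stats::coef(stats::lm.fit(cbind(1, t[keep]), y[keep]))[2L])
}

#' Inhibited and post-induction oxygen-uptake rates
#'
#' `R_inh` is the least-squares slope of the uptake over the window
#' `[0.15 tau, 0.85 tau]` after injection, skipping the injection transient
#' and the curvature near the breakpoint; `R_ox2` is the slope over
#' `[1.1 tau, end]` (`NA` when fewer than 5 points lie past the
#' breakpoint). When no induction period exists (`tau` absent), the
#' whole post-injection record is used for `R_inh` (a retardation rate) and
#' `R_ox2` is `NA`.
#'
#' @param trace An [o2_trace()].
#' @param tau Induction period (s, from injection), e.g. from
#'   [estimate_tau()]; `NULL`/`NA` for retarded traces.
#' @param window Fractions of `tau` bounding the induction-phase window.
#' @return List with `R_inh` and `R_ox2` (M s^-1).
#' @export
estimate_phase_rates <- function(trace, tau = NULL, window = c(0.15, 0.85)) {
  fr <- post_injection_frame(trace)
  if (is.null(tau) || !is.finite(tau)) {
    return(list(R_inh = window_slope(fr$t, fr$y, 0, max(fr$t)), R_ox2 = NA_real_))
  }
  list(R_inh = window_slope(fr$t, fr$y, window[1L] * tau, window[2L] * tau),
       R_ox2 = tryCatch(window_slope(fr$t, fr$y, 1.1 * tau, max(fr$t)),
                        autoxkin_insufficient_data = function(e) NA_real_))
}

#' Initiation rate from a reference antioxidant of known stoichiometry
#'
#' The induction period relates the initiation flux, the antioxidant loading
#' and its stoichiometric factor: `tau = n [ArOH]0 / R_i`. A reference
#' compound of known `n` (the alpha-tocopherol analogue PMHC, n = 2)
#' therefore calibrates `R_i = n_ref conc_ref / tau_ref`.
#'
#' @param tau_ref Induction period of the reference run (s).
#' @param n_ref Stoichiometric factor of the reference antioxidant.
#' @param conc_ref Reference antioxidant concentration (M).
#' @return Initiation rate (M s^-1).
#' @export
compute_Ri <- function(tau_ref, n_ref = 2, conc_ref = 1e-6) {
  if (!is.finite(tau_ref) || tau_ref <= 0) {
    stop_autoxkin("autoxkin_division_error", "tau_ref must be > 0")
  }
  stopifnot(n_ref > 0, conc_ref > 0)
  n_ref * conc_ref / tau_ref
}

#' Stoichiometric factor from an induction period
#'
#' Inverts the same relation as [compute_Ri()]: `n = R_i tau / conc`.
#'
#' @param tau Induction period (s).
#' @param R_i Initiation rate (M s^-1).
#' @param conc Antioxidant concentration (M).
#' @return Stoichiometric factor (dimensionless).
#' @export
compute_n <- function(tau, R_i, conc) {
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop_autoxkin("autoxkin_division_error", "conc must be > 0")
  }
  R_i * tau / conc
}

#' Inhibition rate constant from the induction-phase uptake shape
#'
#' During the induction period the integrated inhibited-rate law predicts
#' `Delta[O2](t) = (k_p [LH] / k_inh) * (-log(1 - t / tau))`. Regressing the
#' post-injection uptake against `-log(1 - t/tau)` through the origin over
#' the window `[0.15 tau, 0.85 tau]` gives the slope `k_p [LH] / k_inh`,
#' hence `k_inh`.
#'
#' @param trace An [o2_trace()].
#' @param tau Induction period (s, from injection).
#' @param k_p Propagation rate constant (M^-1 s^-1).
#' @param LH Lipid concentration (M).
#' @param window Fractions of `tau` bounding the fit window.
#' @return Inhibition rate constant (M^-1 s^-1).
#' @export
estimate_kinh <- function(trace, tau, k_p, LH, window = c(0.15, 0.85)) {
  stopifnot(is.finite(tau), tau > 0, k_p > 0, LH > 0)
  fr <- post_injection_frame(trace)
  keep <- fr$t >= window[1L] * tau & fr$t <= window[2L] * tau
  if (sum(keep) < 5L) {
    stop_autoxkin("autoxkin_insufficient_data",
                  "induction-phase window holds fewer than 5 points")
  }
  x <- -log1p(-fr$t[keep] / tau)
  y <- fr$y[keep]
  slope <- sum(x * y) / sum(x * x)
  if (!is.finite(slope) || slope <= 0) {
    stop_autoxkin("autoxkin_fit_failure",
                  "non-positive regression slope; cannot invert for k_inh")
  }
  k_p * LH / slope
}

#' Capacity-corrected inhibition rate constant
#'
#' The integrated rate law underlying [estimate_kinh()] assumes the
#' antioxidant traps two radicals. For compounds with larger capacity
#' (n > 2) the uncorrected value is a minimal, apparent constant; scaling by
#' `n / 2` restores the per-event rate constant.
#'
#' @param k_inh Apparent inhibition rate constant (M^-1 s^-1).
#' @param n Stoichiometric factor.
#' @return Corrected inhibition rate constant (M^-1 s^-1).
#' @export
correct_kinh <- function(k_inh, n) {
  stopifnot(n > 0)
  k_inh * n / 2
}

#' Kinetic chain length during inhibition
#'
#' `nu_inh = R_inh / R_i`: the number of propagation turnovers per initiated
#' radical while the antioxidant is active.
#'
#' @param R_inh Inhibited uptake rate (M s^-1).
#' @param R_i Initiation rate (M s^-1).
#' @return Kinetic chain length (dimensionless).
#' @export
compute_nu <- function(R_inh, R_i) {
  if (!is.finite(R_i) || R_i <= 0) {
    stop_autoxkin("autoxkin_division_error", "R_i must be > 0")
  }
  R_inh / R_i
}

#' Co-antioxidant stoichiometric factor from a mixture run
#'
#' For an equimolar mixture with a reference antioxidant, the co-antioxidant
#' stoichiometry follows from the induction-period prolongation:
#' `n_co = R_i (tau_mix - tau_ref) / conc_co`.
#'
#' @param tau_mix Induction period of the mixture run (s).
#' @param tau_ref Induction period of the reference antioxidant alone (s).
#' @param R_i Initiation rate (M s^-1).
#' @param conc_co Co-antioxidant concentration (M).
#' @return Co-antioxidant stoichiometric factor; negative values (mixture
#'   shorter than the reference alone) are returned with a warning.
#' @export
synergy_n <- function(tau_mix, tau_ref, R_i, conc_co) {
  stopifnot(conc_co > 0)
  if (is.finite(tau_mix) && is.finite(tau_ref) && tau_mix < tau_ref) {
    warning("tau_mix < tau_ref: negative co-antioxidant stoichiometry",
            call. = FALSE)
  }
  R_i * (tau_mix - tau_ref) / conc_co
}

#' Classify a run as inhibition, retardation, or no activity
#'
#' Operational thresholds on the slow-down factor `R_ox / R_inh` computed
#' against the matched uninhibited run: a genuine induction period
#' (breakpoint found) with slow-down >= `inhibition_min` is "inhibition";
#' slow-down >= `retardation_min` without a qualifying breakpoint is
#' "retardation"; anything else is "none".
#'
#' @param slowdown Ratio `R_ox / R_inh` against the matched uninhibited run.
#' @param breakpoint_found Logical from [estimate_tau()].
#' @param inhibition_min,retardation_min Classification thresholds.
#' @return `"inhibition"`, `"retardation"`, or `"none"`.
#' @export
classify <- function(slowdown, breakpoint_found,
                     inhibition_min = 3, retardation_min = 1.3) {
  if (!is.finite(slowdown)) {
    stop_autoxkin("autoxkin_cannot_classify",
                  "slow-down factor unavailable (missing uninhibited reference)")
  }
  if (isTRUE(breakpoint_found) && slowdown >= inhibition_min) "inhibition"
  else if (slowdown >= retardation_min) "retardation"
  else "none"
}

#' Analyse a set of paired oxygen-uptake traces
#'
#' Orchestrates the whole inference pipeline over a collection of traces and
#' emits one metrics row per trace, mirroring the layout of a kinetic summary
#' table: induction period (and bootstrap SD), stoichiometric factor,
#' inhibited rate, slow-down factor, inhibition rate constant (apparent and
#' n/2-corrected), kinetic chain length, classification, and - for mixture
#' runs - the additivity comparison and co-antioxidant stoichiometry.
#'
#' Within each (medium, pH) condition the initiation rate is calibrated from
#' the run of the `reference` antioxidant (known `n_ref`), and the slow-down
#' factor is taken against the matched uninhibited run.
#'
#' @param traces List of [o2_trace()] objects. Each trace's metadata must
#'   carry `medium`, `pH` and a `compounds` data frame (`name`, `conc0`);
#'   uninhibited runs have an empty roster.
#' @param reference Name of the reference antioxidant (default `"PMHC"`).
#' @param n_ref Stoichiometric factor of the reference.
#' @param k_p Propagation constant; defaults per-trace to the medium value.
#' @param LH Lipid concentration (M); defaults to trace metadata, else
#'   2.74e-3.
#' @param n_boot Bootstrap replicates for `tau_sd`.
#' @param seed Seed for the bootstrap.
#' @param inhibition_min,retardation_min Thresholds passed to [classify()].
#' @return A data frame with one row per trace.
#' @export
analyze_experiment <- function(traces, reference = "PMHC", n_ref = 2,
                               k_p = NULL, LH = NULL,
                               n_boot = 200, seed = NULL,
                               inhibition_min = 3, retardation_min = 1.3) {
  if (inherits(traces, "o2_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L)
  info <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    md <- tr$metadata
    cmp <- md$compounds
    if (is.null(cmp)) cmp <- data.frame(name = character(), conc0 = numeric())
    label <- names(traces)[i]
    if (is.null(label) || !nzchar(label)) {
      label <- if (nrow(cmp)) paste(cmp$name, collapse = "/") else "uninhibited"
    }
    list(trace = tr, medium = md$medium %||% NA_character_,
         pH = md$pH %||% NA_real_, compounds = cmp, label = label)
  })
  key <- vapply(info, function(x) paste(x$medium, x$pH), character(1))
  n_cmp <- vapply(info, function(x) nrow(x$compounds), integer(1))

  # per-condition uninhibited rate and reference-calibrated R_i
  cond <- unique(key)
  R_ox_by <- stats::setNames(rep(NA_real_, length(cond)), cond)
  R_i_by <- R_ox_by
  tau_ref_by <- R_ox_by
  for (cd in cond) {
    iu <- which(key == cd & n_cmp == 0L)
    if (length(iu)) {
      tr <- info[[iu[1L]]]$trace
      fr <- post_injection_frame(tr)
      R_ox_by[cd] <- window_slope(fr$t, fr$y, 0.1 * max(fr$t), max(fr$t))
    }
    ir <- which(key == cd & n_cmp == 1L &
                  vapply(info, function(x) {
                    nrow(x$compounds) == 1L && x$compounds$name[1L] == reference
                  }, logical(1)))
    if (length(ir)) {
      x <- info[[ir[1L]]]
      ft <- estimate_tau(x$trace, n_boot = 0)
      if (ft$breakpoint_found) {
        tau_ref_by[cd] <- ft$tau
        R_i_by[cd] <- compute_Ri(ft$tau, n_ref, x$compounds$conc0[1L])
      }
    }
    if (!is.finite(R_i_by[cd]) && any(key == cd & n_cmp > 0L)) {
      warning(sprintf("no usable %s reference at condition '%s': R_i unavailable",
                      reference, cd), call. = FALSE)
    }
  }

  # solo induction periods per condition, for mixture additivity
  rows <- vector("list", length(info))
  tau_solo <- list()
  fits <- vector("list", length(info))
  for (i in seq_along(info)) {
    x <- info[[i]]
    if (n_cmp[i] >= 1L) {
      fits[[i]] <- estimate_tau(x$trace, n_boot = n_boot, seed = seed)
      if (n_cmp[i] == 1L && fits[[i]]$breakpoint_found) {
        tau_solo[[paste(key[i], x$compounds$name[1L])]] <- fits[[i]]$tau
      }
    }
  }

  for (i in seq_along(info)) {
    x <- info[[i]]
    cd <- key[i]
    R_ox <- R_ox_by[cd]
    R_i <- R_i_by[cd]
    kp_i <- if (is.null(k_p)) {
      if (x$medium %in% c("micelle", "liposome")) kp_for_medium(x$medium) else 36
    } else k_p
    LH_i <- if (is.null(LH)) x$trace$metadata$LH0 %||% 2.74e-3 else LH
    row <- data.frame(label = x$label, medium = x$medium, pH = x$pH,
                      n_compounds = n_cmp[i],
                      R_ox = R_ox, R_i = R_i,
                      tau = NA_real_, tau_sd = NA_real_, n = NA_real_,
                      R_inh = NA_real_, slowdown = NA_real_,
                      k_inh = NA_real_, k_inh_corrected = NA_real_,
                      nu_inh = NA_real_, classification = NA_character_,
                      tau_sum = NA_real_, hyper_ratio = NA_real_,
                      n_co = NA_real_, synergy_complete = NA,
                      stringsAsFactors = FALSE)
    if (n_cmp[i] == 0L) {
      rows[[i]] <- row
      next
    }
    ft <- fits[[i]]
    tau <- if (ft$breakpoint_found) ft$tau else NA_real_
    rates <- estimate_phase_rates(x$trace, tau)
    row$tau <- tau
    row$tau_sd <- ft$tau_sd
    row$R_inh <- rates$R_inh
    row$slowdown <- if (is.finite(R_ox)) R_ox / rates$R_inh else NA_real_
    row$classification <- tryCatch(
      classify(row$slowdown, ft$breakpoint_found,
               inhibition_min, retardation_min),
      autoxkin_cannot_classify = function(e) NA_character_)
    if (is.finite(R_i)) row$nu_inh <- compute_nu(rates$R_inh, R_i)
    if (n_cmp[i] == 1L) {
      conc <- x$compounds$conc0[1L]
      if (is.finite(R_i) && is.finite(tau)) row$n <- compute_n(tau, R_i, conc)
      if (is.finite(tau)) {
        row$k_inh <- tryCatch(estimate_kinh(x$trace, tau, kp_i, LH_i),
                              autoxkin_error = function(e) NA_real_)
        if (is.finite(row$k_inh) && is.finite(row$n)) {
          row$k_inh_corrected <- correct_kinh(row$k_inh, max(row$n, 2))
        }
      }
    } else {
      solos <- unlist(lapply(x$compounds$name,
                             function(nm) tau_solo[[paste(cd, nm)]]))
      if (length(solos) == nrow(x$compounds) && is.finite(tau)) {
        row$tau_sum <- sum(solos)
        row$hyper_ratio <- tau / row$tau_sum
        row$synergy_complete <- TRUE
      } else {
        row$synergy_complete <- FALSE
      }
      co <- x$compounds[x$compounds$name != reference, , drop = FALSE]
      if (is.finite(R_i) && is.finite(tau) && is.finite(tau_ref_by[cd]) &&
          nrow(co) == 1L) {
        row$n_co <- synergy_n(tau, tau_ref_by[cd], R_i, co$conc0[1L])
        row$n <- row$n_co
      }
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Write a metrics table as delimited text
#'
#' Mirrors the summary-table layout (minutes and nM/s for readability) with
#' '#'-prefixed metadata lines.
#'
#' @param metrics Data frame from [analyze_experiment()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(metrics, path, sep = ",") {
  out <- data.frame(label = metrics$label, medium = metrics$medium,
                    pH = metrics$pH,
                    tau_min = metrics$tau / 60,
                    tau_sd_min = metrics$tau_sd / 60,
                    n = metrics$n,
                    R_inh_nM_s = metrics$R_inh * 1e9,
                    slowdown = metrics$slowdown,
                    k_inh_M_s = metrics$k_inh,
                    k_inh_corrected_M_s = metrics$k_inh_corrected,
                    nu_inh = metrics$nu_inh,
                    classification = metrics$classification,
                    tau_sum_min = metrics$tau_sum / 60,
                    hyper_ratio = metrics$hyper_ratio,
                    n_co = metrics$n_co)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# autoxkin metrics table",
               "# units: tau min, rates nM/s, k_inh M^-1 s^-1",
               sprintf("# generated: n_rows %d", nrow(out))), con)
  utils::write.table(format(out, digits = 6, trim = TRUE), con, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
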