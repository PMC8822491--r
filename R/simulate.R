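#' Signal a classed package error
#' @noRd
stop_autoxkin <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "autoxkin_error")))
}

#' Build the species bookkeeping for a system
#'
#' Every antioxidant contributes a phenol/phenoxyl pair per coupling
#' generation: generation 0 is the parent compound; generations 1..depth are
#' dimer phenols counted as phenol-equivalent trapping units (one coupling
#' event of two phenoxyls yields one dimer carrying two recovered hydroxyls,
#' i.e. two units of the next generation).
#' @noRd
species_plan <- function(system, params) {
  units <- list()
  for (i in seq_along(system$antioxidants)) {
    a <- system$antioxidants[[i]]
    depth <- if (a$dimerizes) a$cascade_depth else 0L
    for (g in 0:depth) {
      units[[length(units) + 1L]] <- list(
        ao = i, gen = g,
        name = if (g == 0L) a$name else sprintf("%s_dim%d", a$name, g),
        kinh = if (g == 0L) a$k_inh else a$dimer_k_inh,
        couples = a$dimerizes,
        conc0 = if (g == 0L) a$conc0 else 0,
        regenerable = a$regenerable && g == 0L,
        parent0 = g == 0L)
    }
  }
  n <- length(units)
  plan <- list(
    n_units = n,
    names = vapply(units, `[[`, character(1), "name"),
    kinh = vapply(units, `[[`, numeric(1), "kinh"),
    couples = vapply(units, `[[`, logical(1), "couples"),
    conc0 = vapply(units, `[[`, numeric(1), "conc0"),
    gen0 = vapply(units, `[[`, logical(1), "parent0"),
    regen = vapply(units, `[[`, logical(1), "regenerable"),
    ao = vapply(units, `[[`, integer(1), "ao"),
    gen = vapply(units, `[[`, integer(1), "gen"))
  # coupling target: unit index of (same antioxidant, gen + 1), NA if none
  plan$target <- rep(NA_integer_, n)
  if (n) {
    key <- paste(plan$ao, plan$gen + 1L)
    have <- paste(plan$ao, plan$gen)
    plan$target <- match(key, have)
  }
  # regeneration pairs: regenerable parent radical x other parent phenols
  pairs <- NULL
  if (params$k_r > 0 && n) {
    for (i in which(plan$regen)) {
      for (j in which(plan$gen0 & plan$ao != plan$ao[i])) {
        pairs <- rbind(pairs, c(i, j))
      }
    }
  }
  plan$regen_pairs <- pairs
  plan
}

#' Simulate a noiseless oxygen-uptake trace
#'
#' Integrates the deterministic reaction network of azo-initiated lipid
#' peroxidation: a constant initiation flux `R_i` delivering peroxyl radicals
#' (initiation is lumped; the azo decomposition itself is not modelled),
#' propagation LOO. + LH (rate `k_p`, one O2 consumed per turnover because
#' the carbon radical is oxygenated quasi-instantaneously), peroxyl
#' self-termination (`two_kt`), chain-breaking H transfer from each phenol
#' unit (`k_inh`), phenoxyl + peroxyl cross-termination (`k_rad_cross`),
#' phenoxyl self-decay (`two_k_AO`), phenoxyl coupling to dimer phenols
#' (`k_dim`, for `dimerizes` antioxidants), first-order antioxidant
#' decomposition (`k_dec`) and co-antioxidant regeneration (`k_r`).
#'
#' All antioxidants are present from t = 0; use [generate_trace()] for the
#' experimental protocol where they are injected after 10% O2 depletion.
#'
#' @param system An [experiment_system()].
#' @param params A [reaction_parameters()]; defaults to the medium-matched
#'   propagation constant.
#' @param t_end Integration end time (s).
#' @param dt_out Output sampling interval (s).
#' @param rtol,atol Integrator tolerances (stiff-safe defaults).
#'
#' @return An [o2_trace()] with a species ledger in `attr(, "ledger")`:
#'   a data frame with one column per species (LH, LOO, each phenol unit and
#'   its radical) plus the cumulative O2 uptake (`dO2`), cumulative
#'   terminated radicals (`terminated`) and hydroperoxide formed (`LOOH`).
#' @export
simulate_uptake <- function(system, params = NULL, t_end, dt_out = 5,
                            rtol = 1e-10, atol = 1e-16) {
  stopifnot(inherits(system, "experiment_system"))
  if (is.null(params)) {
    params <- reaction_parameters(k_p = kp_for_medium(system))
  }
  stopifnot(inherits(params, "reaction_parameters"))
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (length(system$antioxidants) == 0L && params$two_kt <= 0 &&
      system$R_i > 0) {
    stop("two_kt must be > 0 for an uninhibited simulation", call. = FALSE)
  }

  times <- seq(0, t_end, by = dt_out)
  if (t_end - times[length(times)] > 1e-6 * dt_out) times <- c(times, t_end)
  out <- integrate_network(system, params, times)
  ledger <- as.data.frame(out)
  names(ledger)[1L] <- "time"
  tr <- o2_trace(times = ledger$time, o2_consumed = ledger$dO2,
                 injection_time = 0,
                 metadata = list(medium = system$medium,
                                 pH = system$pH_label,
                                 R_i = system$R_i,
                                 LH0 = system$LH0,
                                 k_p = params$k_p,
                                 compounds = roster_frame(system),
                                 source = "simulate_uptake"))
  attr(tr, "ledger") <- ledger
  tr
}

#' @noRd
roster_frame <- function(system) {
  if (!length(system$antioxidants)) {
    return(data.frame(name = character(), conc0 = numeric()))
  }
  data.frame(name = vapply(system$antioxidants, `[[`, character(1), "name"),
             conc0 = vapply(system$antioxidants, `[[`, numeric(1), "conc0"))
}

#' Core integration over explicit output times, returning the deSolve matrix
#' @noRd
integrate_network <- function(system, params, times, y0 = NULL,
                              rtol = 1e-10, atol = 1e-16) {
  plan <- species_plan(system, params)
  n <- plan$n_units
  i_LH <- 1L; i_LOO <- 2L
  i_AH <- if (n) 2L + seq_len(n) else integer()
  i_Ar <- if (n) 2L + n + seq_len(n) else integer()
  i_O2 <- 3L + 2L * n   # cumulative uptake
  i_term <- i_O2 + 1L
  i_looh <- i_O2 + 2L

  if (is.null(y0)) {
    y0 <- numeric(i_looh)
    y0[i_LH] <- system$LH0
    if (n) y0[i_AH] <- plan$conc0
  }
  names(y0) <- c("LH", "LOO",
                 if (n) paste0("AH_", plan$names),
                 if (n) paste0("Ar_", plan$names),
                 "dO2", "terminated", "LOOH")

  R_i <- system$R_i
  kx <- params$k_rad_cross
  pr <- plan$regen_pairs

  deriv <- function(t, y, p) {
    y <- pmax(y, 0)
    LH <- y[i_LH]; LOO <- y[i_LOO]
    dy <- numeric(length(y))
    r_prop <- params$k_p * LH * LOO
    dy[i_LH] <- -r_prop
    dLOO <- R_i - params$two_kt * LOO^2
    dterm <- params$two_kt * LOO^2
    if (n) {
      AH <- y[i_AH]; Ar <- y[i_Ar]
      r_inh <- plan$kinh * AH * LOO
      r_cross <- kx * Ar * LOO
      r_self <- params$two_k_AO * Ar^2
      r_coup <- ifelse(plan$couples, params$k_dim * Ar^2, 0)
      dAH <- -r_inh
      dAH[plan$gen0] <- dAH[plan$gen0] - params$k_dec * AH[plan$gen0]
      dAr <- r_inh - r_cross - r_self - r_coup
      # one coupling event consumes two phenoxyls of generation g and yields
      # one dimer = two phenol-equivalent units of generation g + 1
      has_t <- which(!is.na(plan$target) & r_coup > 0)
      if (length(has_t)) {
        dAH[plan$target[has_t]] <- dAH[plan$target[has_t]] + r_coup[has_t]
      }
      if (!is.null(pr)) {
        rr <- params$k_r * Ar[pr[, 1L]] * AH[pr[, 2L]]
        for (q in seq_len(nrow(pr))) {
          dAr[pr[q, 1L]] <- dAr[pr[q, 1L]] - rr[q]
          dAH[pr[q, 1L]] <- dAH[pr[q, 1L]] + rr[q]
          dAH[pr[q, 2L]] <- dAH[pr[q, 2L]] - rr[q]
          dAr[pr[q, 2L]] <- dAr[pr[q, 2L]] + rr[q]
        }
      }
      dLOO <- dLOO - sum(r_inh) - sum(r_cross)
      dterm <- dterm + 2 * sum(r_cross) + sum(r_self) + sum(r_coup)
      dy[i_AH] <- dAH
      dy[i_Ar] <- dAr
      dy[i_looh] <- r_prop + sum(r_inh)
    } else {
      dy[i_looh] <- r_prop
    }
    dy[i_LOO] <- dLOO
    dy[i_term] <- dterm
    dy[i_O2] <- r_prop + if (params$include_initiator_O2) R_i else 0
    list(dy)
  }

  out <- deSolve::lsoda(y = y0, times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  check_integration(out, names(y0))
  out
}

#' @noRd
check_integration <- function(out, species) {
  m <- as.matrix(out[, -1L, drop = FALSE])
  bad <- colSums(!is.finite(m)) > 0
  if (any(bad)) {
    stop_autoxkin("autoxkin_integration_failure",
                  sprintf("non-finite state for species: %s",
                          paste(species[bad], collapse = ", ")))
  }
  neg <- apply(m, 2L, min) < -1e-9
  if (any(neg)) {
    stop_autoxkin("autoxkin_integration_failure",
                  sprintf("negative concentration beyond tolerance for: %s",
                          paste(species[neg], collapse = ", ")))
  }
  invisible(out)
}

#' Steady-state uninhibited peroxidation rate (closed-form oracle)
#'
#' The long-chain steady-state limit of the uninhibited network:
#' R_ox = k_p [LH] sqrt(R_i / 2k_t). Used as an independent check on the
#' integrator, not derived from it.
#'
#' @inheritParams simulate_uptake
#' @return Oxygen-uptake rate (M s^-1).
#' @export
steady_state_rox <- function(system, params = NULL) {
  if (is.null(params)) params <- reaction_parameters(kp_for_medium(system))
  if (params$two_kt <= 0) {
    stop_autoxkin("autoxkin_undefined_oracle",
                  "steady-state rate undefined for two_kt = 0")
  }
  params$k_p * system$LH0 * sqrt(system$R_i / params$two_kt)
}

#' Quasi-steady-state inhibited peroxidation rate (closed-form oracle)
#'
#' For a single non-dimerizing antioxidant trapping two radicals (reactions
#' 6 + 7), the inhibited-phase uptake rate is
#' R_inh = k_p [LH] R_i / (2 k_inh [ArOH]).
#'
#' @param k_p Propagation constant (M^-1 s^-1).
#' @param LH Lipid concentration (M).
#' @param R_i Initiation flux (M s^-1).
#' @param k_inh Inhibition rate constant (M^-1 s^-1).
#' @param conc Antioxidant concentration (M).
#' @return Oxygen-uptake rate (M s^-1).
#' @export
inhibited_slope_oracle <- function(k_p, LH, R_i, k_inh, conc) {
  k_p * LH * R_i / (2 * k_inh * conc)
}

#' Closed-form oxygen uptake during the induction period
#'
#' The integrated inhibited-rate law: at time `t` after antioxidant addition
#' (and within the induction period `tau`),
#' `Delta[O2](t) = -(k_p [LH] / k_inh) * log(1 - t / tau)`.
#' This is both the exact-kinetics trace generator used for testing and the
#' model inverted by [estimate_kinh()].
#'
#' @param t Time(s) since antioxidant addition (s); vectorised. Must satisfy
#'   `0 <= t < tau`.
#' @param tau Induction period (s).
#' @param k_inh Inhibition rate constant (M^-1 s^-1).
#' @param k_p Propagation rate constant (M^-1 s^-1).
#' @param LH Lipid concentration (M).
#' @return Cumulative O2 consumption (M).
#' @export
closed_form_uptake <- function(t, tau, k_inh, k_p, LH) {
  stopifnot(tau > 0, k_inh > 0)
  if (any(t < 0 | t >= tau)) {
    stop_autoxkin("autoxkin_domain_error",
                  "closed_form_uptake requires 0 <= t < tau")
  }
  -(k_p * LH / k_inh) * log1p(-t / tau)
}

#' Effective stoichiometric factor of a simulated antioxidant
#'
#' Simulates a run with the single named antioxidant, locates the induction
#' breakpoint with [estimate_tau()], and returns
#' `n_eff = R_i * tau / conc0`. Non-dimerizing phenols give n close to 2
#' (reactions 6 + 7); trapping-competent dimer cascades raise it by up to
#' one radical per realised coupling generation.
#'
#' @inheritParams simulate_uptake
#' @param antioxidant_name Name of the antioxidant to test; defaults to the
#'   single antioxidant in the system roster.
#' @param t_end Optional simulation horizon (s); defaults to twice the
#'   largest possible induction period for the cascade depth.
#' @return Effective stoichiometric factor (dimensionless).
#' @export
effective_stoichiometry <- function(system, params = NULL,
                                    antioxidant_name = NULL, t_end = NULL) {
  if (is.null(params)) params <- reaction_parameters(kp_for_medium(system))
  roster <- system$antioxidants
  if (is.null(antioxidant_name)) {
    if (length(roster) != 1L) {
      stop("antioxidant_name required when the roster is not a single compound",
           call. = FALSE)
    }
    a <- roster[[1L]]
  } else {
    nm <- vapply(roster, `[[`, character(1), "name")
    a <- roster[[match(antioxidant_name, nm)]]
    if (is.null(a)) stop("unknown antioxidant", call. = FALSE)
    system$antioxidants <- list(a)
  }
  if (system$R_i <= 0 || a$conc0 <= 0) {
    stop("R_i and conc0 must be > 0", call. = FALSE)
  }
  if (is.null(t_end)) {
    n_max <- 2 + if (a$dimerizes) a$cascade_depth else 0
    t_end <- 2 * n_max * a$conc0 / system$R_i
  }
  tr <- simulate_uptake(system, params, t_end = t_end,
                        dt_out = max(t_end / 2000, 1))
  fit <- estimate_tau(tr, n_boot = 0)
  # a genuine induction phase must suppress the chain well below the
  # uninhibited steady rate; otherwise the breakpoint is spurious (e.g. the
  # radical build-up transient of a nearly uninhibited run)
  suppressed <- fit$breakpoint_found &&
    fit$slope1 < steady_state_rox(system, params) / 3
  n_eff <- system$R_i * fit$tau / a$conc0
  # a breakpoint implying less than half a radical trapped per molecule is
  # the radical build-up transient, not an induction period
  if (!suppressed || !is.finite(n_eff) || n_eff < 0.5) {
    stop_autoxkin("autoxkin_no_induction",
                  sprintf("no detectable induction breakpoint for %s", a$name))
  }
  n_eff
}

#' Radical conservation defect of a simulated ledger
#'
#' At every output time the initiated radicals must be accounted for:
#' `R_i t = [LOO.] + sum of phenoxyls + cumulative terminated`, within the
#' integration tolerance. Returns the maximum absolute defect (M).
#'
#' @param trace A trace produced by [simulate_uptake()] (needs its ledger).
#' @param R_i Initiation flux used for the run (M s^-1); taken from the trace
#'   metadata when omitted.
#' @return Maximum absolute radical-balance defect (M).
#' @export
radical_balance_defect <- function(trace, R_i = NULL) {
  led <- attr(trace, "ledger")
  if (is.null(led)) stop("trace carries no species ledger", call. = FALSE)
  if (is.null(R_i)) R_i <- trace$metadata$R_i
  rad_cols <- grep("^Ar_", names(led), value = TRUE)
  present <- led$LOO + if (length(rad_cols)) {
    rowSums(led[, rad_cols, drop = FALSE])
  } else 0
  max(abs(R_i * led$time - (present + led$terminated)))
}

#' Write a species ledger to delimited text
#'
#' One column per species, a header row of species names, and '#'-prefixed
#' metadata lines (units, parameters) ahead of the data.
#'
#' @param trace A trace from [simulate_uptake()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(trace, path, sep = ",") {
  led <- attr(trace, "ledger")
  if (is.null(led)) stop("trace carries no species ledger", call. = FALSE)
  md <- trace$metadata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# autoxkin species ledger",
               "# units: time s, concentrations M",
               sprintf("# medium: %s", md$medium %||% "NA"),
               sprintf("# pH: %s", format(md$pH %||% NA)),
               sprintf("# R_i: %s", format(md$R_i %||% NA))), con)
  utils::write.table(led, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
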