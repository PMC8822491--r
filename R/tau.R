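#' Two-segment continuous piecewise-linear fit
#'
#' Model y = b0 + b1 t + b2 (t - c)+ fitted by least squares, with an
#' exhaustive scan of the breakpoint c over the sampling grid followed by a
#' continuous refinement between the neighbouring grid points. Data are
#' standardised internally, so the fit is exactly equivariant under time
#' shifts and uptake rescaling.
#' @noRd
pw_fit <- function(t, y, refine = TRUE, min_seg = 3L) {
  N <- length(t)
  mt <- mean(t); st <- stats::sd(t)
  my <- mean(y); sy <- stats::sd(y)
  if (!is.finite(sy) || sy == 0) sy <- 1
  ts <- (t - mt) / st
  ys <- (y - my) / sy

  pre1 <- cumsum(rep(1, N)); preT <- cumsum(ts); preT2 <- cumsum(ts^2)
  preY <- cumsum(ys); preTY <- cumsum(ts * ys)
  S0 <- N; St <- preT[N]; Stt <- preT2[N]
  Sy <- preY[N]; Sty <- preTY[N]; Syy <- sum(ys^2)

  sse_at <- function(cc, j) {
    # j = number of points with t <= cc
    n1 <- S0 - j
    T1 <- St - preT[j]; T2 <- Stt - preT2[j]
    Y1 <- Sy - preY[j]; TY <- Sty - preTY[j]
    Sz <- T1 - cc * n1
    Szz <- T2 - 2 * cc * T1 + cc^2 * n1
    Stz <- T2 - cc * T1
    Szy <- TY - cc * Y1
    M11 <- Stt * Szz - Stz^2
    M12 <- St * Szz - Stz * Sz
    M13 <- St * Stz - Stt * Sz
    det <- S0 * M11 - St * M12 + Sz * M13
    if (!is.finite(det) || abs(det) < 1e-12) {
      return(list(sse = Inf, b = c(NA, NA, NA)))
    }
    b0 <- (Sy * M11 - Sty * M12 + Szy * M13) / det
    b1 <- (-Sy * M12 + Sty * (S0 * Szz - Sz^2) -
             Szy * (S0 * Stz - St * Sz)) / det
    b2 <- (Sy * M13 - Sty * (S0 * Stz - St * Sz) +
             Szy * (S0 * Stt - St^2)) / det
    sse <- Syy - (b0 * Sy + b1 * Sty + b2 * Szy)
    list(sse = max(sse, 0), b = c(b0, b1, b2))
  }

  js <- seq.int(min_seg, N - min_seg)
  cc <- ts[js]
  n1 <- S0 - js
  T1 <- St - preT[js]; T2 <- Stt - preT2[js]
  Y1 <- Sy - preY[js]; TY <- Sty - preTY[js]
  Sz <- T1 - cc * n1
  Szz <- T2 - 2 * cc * T1 + cc^2 * n1
  Stz <- T2 - cc * T1
  Szy <- TY - cc * Y1
  M11 <- Stt * Szz - Stz^2
  M12 <- St * Szz - Stz * Sz
  M13 <- St * Stz - Stt * Sz
  det <- S0 * M11 - St * M12 + Sz * M13
  b0 <- (Sy * M11 - Sty * M12 + Szy * M13) / det
  b1 <- (-Sy * M12 + Sty * (S0 * Szz - Sz^2) - Szy * (S0 * Stz - St * Sz)) / det
  b2 <- (Sy * M13 - Sty * (S0 * Stz - St * Sz) + Szy * (S0 * Stt - St^2)) / det
  sse <- Syy - (b0 * Sy + b1 * Sty + b2 * Szy)
  sse[!is.finite(sse) | abs(det) < 1e-12] <- Inf

  k <- which.min(sse)
  jb <- js[k]
  best <- list(c = ts[jb], sse = max(sse[k], 0),
               b = c(b0[k], b1[k], b2[k]))

  if (refine) {
    lo <- ts[max(jb - 1L, 1L)]; hi <- ts[min(jb + 1L, N)]
    if (hi > lo) {
      opt <- stats::optimize(function(cc) {
        sse_at(cc, findInterval(cc, ts))$sse
      }, lower = lo, upper = hi, tol = (hi - lo) * 1e-6)
      if (is.finite(opt$objective) && opt$objective <= best$sse + 1e-15) {
        ref <- sse_at(opt$minimum, findInterval(opt$minimum, ts))
        best <- list(c = opt$minimum, sse = ref$sse, b = ref$b)
      }
    }
  }

    # one-segment reference fit
  den <- S0 * Stt - St^2
  a1 <- (S0 * Sty - St * Sy) / den
  a0 <- (Sy - a1 * St) / S0
  sse1 <- Syy - (a0 * Sy + a1 * Sty)

  fitted_std <- best$b[1] + best$b[2] * ts + best$b[3] * pmax(ts - best$c, 0)
  list(breakpoint = best$c * st + mt,
       slope1 = best$b[2] * sy / st,
       slope2 = (best$b[2] + best$b[3]) * sy / st,
       sse2 = best$sse * sy^2,
       sse1 = max(sse1, 0) * sy^2,
       fitted = fitted_std * sy + my,
       n = N)
}

#' Refine the induction endpoint with the integrated inhibited-rate law
#'
#' The induction phase of an inhibited run follows
#' y(t) = y0 + S * (-log(1 - t/tau)) (linear antioxidant depletion), so tau
#' can be read off directly by fitting that law over a window safely inside
#' the induction period. The window is tied to the current estimate
#' ([lo_frac, hi_frac] * tau) and the fit iterated to self-consistency.
#' Returns NA when the log law does not beat a straight line on the same
#' window (e.g. genuinely piecewise-linear data) or when the refined value
#' leaves the neighbourhood of the detected breakpoint.
#' @noRd
refine_tau_loglaw <- function(t, y, c0, lo_frac = 0.1, hi_frac = 0.75,
                              maxit = 15L) {
  tau <- c0
  opt <- NULL; tw <- NULL; yw <- NULL
  for (i in seq_len(maxit)) {
    w <- t >= lo_frac * tau & t <= hi_frac * tau
    if (sum(w) < 10L) return(NA_real_)
    tw <- t[w]; yw <- y[w]
    tmax <- max(tw)
    sse_log <- function(tau2) {
      x <- -log1p(-tw / tau2)
      sum(.lm.fit(cbind(1, x), yw)$residuals^2)
    }
    opt <- stats::optimize(sse_log, lower = tmax * 1.0001, upper = tmax * 50)
    newtau <- opt$minimum
    conv <- abs(newtau - tau) <= 0.002 * tau
    tau <- newtau
    if (conv) break
  }
  sse_lin <- sum(.lm.fit(cbind(1, tw), yw)$residuals^2)
  if (is.finite(tau) && opt$objective <= sse_lin &&
      tau > 0.4 * c0 && tau < 2.5 * c0) tau else NA_real_
}

#' Estimate the induction period from an oxygen-uptake trace
#'
#' Fits a continuous two-segment piecewise-linear model (induction slope,
#' post-induction slope) to the post-injection part of the trace by least
#' squares, scanning every candidate breakpoint on the sampling grid and then
#' refining continuously. The induction period `tau` is the breakpoint
#' abscissa measured from the injection time. A breakpoint is accepted only
#' when the two-segment model beats the single straight line by a clear
#' margin (BIC difference >= `bic_margin`) and the post-induction slope
#' exceeds the induction slope by at least `slope_ratio`; otherwise the trace
#' is flagged as having no induction period (retardation or no activity).
#'
#' The piecewise-linear stage detects the breakpoint and supplies the two
#' phase slopes, but on mechanistic traces it is biased: the chain rate
#' recovers gradually after the antioxidant is exhausted (radical
#' re-equilibration makes the post segment convex) and the induction phase
#' itself is convex (integrated inhibited-rate law), so a straight-line
#' breakpoint drifts with the record length. Two corrections are applied:
#' the linear fit self-truncates to `(1 + post_window) * tau` until stable,
#' and the accepted breakpoint is then refined by fitting the integrated
#' inhibited-rate law `y = y0 + S * (-log(1 - t/tau))` over a window safely
#' inside the induction period, which reads off the antioxidant-exhaustion
#' time directly. The refinement is used only when the log law actually
#' beats a straight line on that window, so exactly piecewise-linear traces
#' keep the scanned breakpoint.
#'
#' `tau_sd` is obtained by residual-resampling bootstrap: residuals of the
#' final fit are resampled with replacement, added back to the fitted
#' curve, and tau re-estimated.
#'
#' @param trace An [o2_trace()]. If `injection_time` is missing, times are
#'   analysed from t = 0 with a warning.
#' @param n_boot Bootstrap replicates for `tau_sd` (0 skips the bootstrap).
#' @param seed Optional integer seed making the bootstrap reproducible
#'   without touching the global RNG stream.
#' @param bic_margin Required BIC improvement of the two-segment model.
#' @param slope_ratio Required ratio of post-induction to induction slope.
#' @param post_window Fraction of the current breakpoint estimate retained
#'   past the breakpoint during the self-truncating refits.
#' @return A list of class `tau_fit`: `tau`, `tau_sd` (s), logical
#'   `breakpoint_found`, the two slopes (M s^-1) and fit diagnostics.
#' @export
estimate_tau <- function(trace, n_boot = 200, seed = NULL,
                         bic_margin = 10, slope_ratio = 1.25,
                         post_window = 0.5) {
  stopifnot(inherits(trace, "o2_trace"))
  if (!is.finite(trace$injection_time)) {
    warning("trace has no injection_time; reporting tau from t = 0",
            call. = FALSE)
    trace$injection_time <- 0
  }
  fr <- post_injection_frame(trace)
  if (length(fr$t) < 20L) {
    stop_autoxkin("autoxkin_insufficient_data",
                  "need >= 20 points after the injection time")
  }
  accepted <- function(fit, N, scale2) {
    if (fit$sse1 <= scale2 * 1e-14) return(FALSE)
    bic2 <- N * log(max(fit$sse2, scale2 * 1e-16) / N) + 4 * log(N)
    bic1 <- N * log(fit$sse1 / N) + 2 * log(N)
    (bic1 - bic2) >= bic_margin &&
      fit$slope2 > slope_ratio * max(fit$slope1, 0) && fit$slope2 > 0
  }
  scale_full <- stats::var(fr$y) * (length(fr$t) - 1)
  fit <- pw_fit(fr$t, fr$y, refine = TRUE)
  found <- accepted(fit, fit$n, scale_full)
  ft <- fr$t; fy <- fr$y
  if (found) {
    for (it in seq_len(8L)) {
      lim <- (1 + post_window) * fit$breakpoint
      keep <- fr$t <= lim
      # keep enough post-breakpoint points to anchor the second slope
      n_post <- sum(fr$t[keep] > fit$breakpoint)
      if (n_post < 10L) {
        keep <- fr$t <= fr$t[min(which(fr$t > fit$breakpoint)[1L] + 9L,
                                 length(fr$t))]
      }
      if (sum(keep) < 20L) break
      new <- pw_fit(fr$t[keep], fr$y[keep], refine = TRUE)
      if (!accepted(new, new$n, stats::var(fr$y[keep]) * (new$n - 1))) break
      conv <- abs(new$breakpoint - fit$breakpoint) <= 0.005 * fit$breakpoint
      fit <- new; ft <- fr$t[keep]; fy <- fr$y[keep]
      if (conv) break
    }
  }
  tau_hat <- fit$breakpoint
  used_loglaw <- FALSE
  if (found) {
    tl <- refine_tau_loglaw(fr$t, fr$y, fit$breakpoint)
    if (is.finite(tl)) {
      tau_hat <- tl
      used_loglaw <- TRUE
    }
  }
  tau_sd <- NA_real_
  if (found && n_boot > 0) {
    if (used_loglaw) {
      w <- fr$t >= 0.1 * tau_hat & fr$t <= 0.75 * tau_hat
      tw <- fr$t[w]; yw <- fr$y[w]
      x <- -log1p(-tw / tau_hat)
      co <- .lm.fit(cbind(1, x), yw)
      fitv <- yw - co$residuals
      tmax <- max(tw)
      taus <- with_seed(seed, {
        vapply(seq_len(n_boot), function(b) {
          yb <- fitv + sample(co$residuals, replace = TRUE)
          stats::optimize(function(tau2) {
            xx <- -log1p(-tw / tau2)
            sum(.lm.fit(cbind(1, xx), yb)$residuals^2)
          }, lower = tmax * 1.0001, upper = tmax * 50)$minimum
        }, numeric(1))
      })
    } else {
      resid <- fy - fit$fitted
      taus <- with_seed(seed, {
        vapply(seq_len(n_boot), function(b) {
          yb <- fit$fitted + sample(resid, replace = TRUE)
          pw_fit(ft, yb, refine = FALSE)$breakpoint
        }, numeric(1))
      })
    }
    tau_sd <- stats::sd(taus)
  }
  structure(list(tau = if (found) tau_hat else NA_real_,
                 tau_sd = tau_sd,
                 breakpoint_found = found,
                 slope1 = fit$slope1, slope2 = fit$slope2,
                 sse2 = fit$sse2, sse1 = fit$sse1, n = fit$n),
            class = "tau_fit")
}

#' @export
print.tau_fit <- function(x, ...) {
  if (x$breakpoint_found) {
    cat(sprintf("<tau_fit> tau = %.4g s (sd %.3g), slopes %.3g -> %.3g M/s\n",
                x$tau, x$tau_sd, x$slope1, x$slope2))
  } else {
    cat(sprintf("<tau_fit> no induction breakpoint (slope %.3g M/s)\n",
                x$slope1))
  }
  invisible(x)
}

#' Evaluate an expression under a temporary RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
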