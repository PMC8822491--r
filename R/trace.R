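#' Construct an oxygen-uptake trace
#'
#' A trace is the primary data object of the pipeline: cumulative O2
#' consumption (M) against time (s, measured from initiator start), plus the
#' antioxidant injection time and free-form provenance metadata.
#'
#' @param times Numeric vector of sampling times (s), strictly increasing,
#'   starting at 0.
#' @param o2_consumed Cumulative O2 uptake (M), same length as `times`;
#'   must be 0 at the first point and non-decreasing unless `noisy = TRUE`.
#' @param injection_time Time (s) at which the antioxidant roster was added;
#'   `NA` for uninhibited runs analysed from t = 0.
#' @param metadata Named list of provenance fields (medium, pH, compounds,
#'   seed, noise sigma, ...). Stored verbatim and round-tripped by the file
#'   format.
#' @param noisy Set `TRUE` for traces carrying sensor noise, which relaxes
#'   the monotonicity invariant.
#'
#' @return An object of class `o2_trace`.
#' @export
o2_trace <- function(times, o2_consumed, injection_time = NA_real_,
                     metadata = list(), noisy = FALSE) {
  times <- as.numeric(times)
  o2_consumed <- as.numeric(o2_consumed)
  if (length(times) != length(o2_consumed)) {
    stop("times and o2_consumed must have equal length", call. = FALSE)
  }
  if (length(times) < 2L) stop("a trace needs >= 2 points", call. = FALSE)
  d <- diff(times)
  if (any(d <= 0)) {
    stop(sprintf("times must be strictly increasing (first violation at row %d)",
                 which(d <= 0)[1L] + 1L), call. = FALSE)
  }
  if (!isTRUE(noisy)) {
    if (abs(o2_consumed[1L]) > 1e-12) {
      stop("o2_consumed must start at 0", call. = FALSE)
    }
    if (any(diff(o2_consumed) < -1e-12)) {
      stop("o2_consumed must be non-decreasing for noiseless traces",
           call. = FALSE)
    }
  }
  structure(list(times = times, o2_consumed = o2_consumed,
                 injection_time = as.numeric(injection_time),
                 metadata = metadata, noisy = isTRUE(noisy)),
            class = "o2_trace")
}

#' @export
print.o2_trace <- function(x, ...) {
  cat(sprintf("<o2_trace> %d points, t = [%.5g, %.5g] s, uptake max %.4g M",
              length(x$times), x$times[1L], x$times[length(x$times)],
              max(x$o2_consumed)))
  if (is.finite(x$injection_time)) {
    cat(sprintf(", injection at %.5g s", x$injection_time))
  }
  cat("\n")
  if (length(x$metadata)) {
    keys <- setdiff(names(x$metadata), "compounds")
    if (length(keys)) {
      cat("  ", paste(sprintf("%s=%s", keys,
                              vapply(x$metadata[keys],
                                     function(v) paste(format(v), collapse = " "),
                                     character(1))),
                      collapse = ", "), "\n", sep = "")
    }
    cmp <- x$metadata$compounds
    if (is.data.frame(cmp) && nrow(cmp)) {
      cat("  compounds: ",
          paste(sprintf("%s (%.3g M)", cmp$name, cmp$conc0), collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Linear interpolation of the uptake at an arbitrary time
#' @noRd
trace_value_at <- function(trace, t) {
  stats::approx(trace$times, trace$o2_consumed, xout = t, rule = 2)$y
}

#' Restrict a trace to times at or after the injection event
#'
#' Returns times re-zeroed at injection and uptake re-zeroed at the
#' (interpolated) uptake level at injection, which is the frame in which the
#' induction period and inhibited rates are defined.
#' @noRd
post_injection_frame <- function(trace) {
  t0 <- trace$injection_time
  if (!is.finite(t0)) t0 <- 0
  keep <- trace$times >= t0 - 1e-9
  y0 <- trace_value_at(trace, t0)
  list(t = trace$times[keep] - t0, y = trace$o2_consumed[keep] - y0)
}
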