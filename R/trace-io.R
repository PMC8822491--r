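#' Write an oxygen-uptake trace to delimited text
#'
#' The on-disk format is plain comma-delimited text: '#'-prefixed metadata
#' header lines (`key: value`, one `compound:` line per antioxidant), then a
#' header row `time_s,o2_consumed_M` and two numeric columns. Values are
#' written with full double precision so `read_trace(write_trace(x))`
#' round-trips exactly.
#'
#' @param trace An [o2_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "o2_trace"))
  md <- trace$metadata
  hdr <- c("# autoxkin oxygen-uptake trace",
           "# time_unit: s",
           "# o2_unit: M",
           sprintf("# injection_time: %.17g", trace$injection_time),
           sprintf("# noisy: %s", trace$noisy))
  scalar_keys <- setdiff(names(md), "compounds")
  for (k in scalar_keys) {
    v <- md[[k]]
    if (is.numeric(v)) v <- sprintf("%.17g", v)
    hdr <- c(hdr, sprintf("# %s: %s", k, paste(v, collapse = " ")))
  }
  cmp <- md$compounds
  if (is.data.frame(cmp) && nrow(cmp)) {
    hdr <- c(hdr, sprintf("# compound: %s %.17g", cmp$name, cmp$conc0))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s,o2_consumed_M", con)
  writeLines(sprintf("%.17g,%.17g", trace$times, trace$o2_consumed), con)
  invisible(path)
}

#' Read an oxygen-uptake trace from delimited text
#'
#' Accepts the format written by [write_trace()]. A `time_unit: min` header
#' (legacy files) converts times and the injection time to seconds on read.
#' A non-monotonic time column raises a format error naming the first
#' offending data row; a missing injection time produces a warning and the
#' induction period is then reported from t = 0.
#'
#' @param path File path.
#' @return An [o2_trace()].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta_lines <- sub("^#\\s*", "", lines[is_meta])
  body <- lines[!is_meta]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("no data rows in trace file", call. = FALSE)

  md <- list()
  compounds <- data.frame(name = character(), conc0 = numeric())
  for (ln in meta_lines) {
    if (!grepl(":", ln, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    if (key == "compound") {
      parts <- strsplit(val, "\\s+")[[1L]]
      compounds <- rbind(compounds,
                         data.frame(name = parts[1L],
                                    conc0 = as.numeric(parts[2L])))
    } else if (nzchar(key)) {
      md[[key]] <- val
    }
  }

  dat <- utils::read.csv(textConnection(body), header = TRUE)
  if (ncol(dat) < 2L) stop("expected two data columns", call. = FALSE)
  times <- as.numeric(dat[[1L]])
  o2 <- as.numeric(dat[[2L]])

  unit <- tolower(md$time_unit %||% "s")
  fac <- switch(unit, s = 1, sec = 1, seconds = 1, min = 60, minutes = 60,
                stop(sprintf("unknown time unit '%s'", unit), call. = FALSE))
  times <- times * fac

  d <- diff(times)
  if (any(d <= 0)) {
    stop(sprintf("non-monotonic time column at data row %d",
                 which(d <= 0)[1L] + 1L), call. = FALSE)
  }

  inj <- suppressWarnings(as.numeric(md$injection_time))
  if (length(inj) == 0L || is.na(inj)) {
    warning("no injection_time in header; tau will be reported from t = 0",
            call. = FALSE)
    inj <- NA_real_
  } else {
    inj <- inj * fac
  }

  noisy <- isTRUE(tolower(md$noisy %||% "false") == "true")
  keep <- setdiff(names(md), c("time_unit", "o2_unit", "injection_time",
                               "noisy"))
  meta <- lapply(md[keep], function(v) {
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  })
  meta$compounds <- compounds
  o2_trace(times = times, o2_consumed = o2, injection_time = inj,
           metadata = meta, noisy = noisy)
}

#' Read a flat key-value run-configuration file
#'
#' Lines of the form `key: value`; '#' comments and blank lines ignored.
#' Numeric-looking values are converted. Nested blocks are expressed with
#' dotted keys (e.g. `noise.sigma: 2e-7`).
#'
#' @param path File path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) {
      stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    }
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    nv <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(nv)) nv else val
  }
  out
}
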