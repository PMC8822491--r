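# End-to-end behaviour of the table-building pipeline on one generated
# condition (liposome, pH 6): uninhibited + PMHC + RSV-like + weak + mixture.
suite_cache <- new.env()
one_condition <- function() {
  if (is.null(suite_cache$s)) {
    suite_cache$s <- generate_benchmark_suite(seed = 17, media = "liposome",
                                              pHs = 6)
    suite_cache$res <- suppressWarnings(
      analyze_experiment(suite_cache$s$traces, n_boot = 0))
  }
  list(s = suite_cache$s, res = suite_cache$res)
}

test_that("the pipeline reproduces the generator truth for one condition", {
  x <- one_condition()
  m <- merge(x$res, x$s$truth, by = "label")
  sing <- m$setting %in% c("PMHC", "RSV")
  expect_true(all(abs(m$tau[sing] / m$tau_true[sing] - 1) < 0.05))
  expect_true(all(abs(m$n[sing] - m$n_true[sing]) < 0.2))
  expect_identical(m$classification[m$setting == "PMHC"], "inhibition")
  expect_identical(m$classification[m$setting == "weak"], "none")
  mix <- m$setting == "PMHC/RSV"
  expect_true(m$synergy_complete[mix])
  expect_equal(m$hyper_ratio[mix], m$hyper_true[mix], tolerance = 0.05)
  expect_equal(m$n_co[mix], m$n_true[mix], tolerance = 0.1)
})

test_that("a lone uninhibited trace yields only the uninhibited rate", {
  x <- one_condition()
  lone <- x$s$traces["liposome_pH6_uninhibited"]
  res <- analyze_experiment(lone, n_boot = 0)
  expect_identical(nrow(res), 1L)
  expect_gt(res$R_ox, 0)
  expect_true(is.na(res$tau) && is.na(res$k_inh) && is.na(res$n))
})

test_that("a mixture without its solo references is flagged incomplete", {
  x <- one_condition()
  sub <- x$s$traces[c("liposome_pH6_uninhibited", "liposome_pH6_PMHC",
                      "liposome_pH6_PMHC_RSV")]
  res <- analyze_experiment(sub, n_boot = 0)
  mix <- res[res$n_compounds == 2L, ]
  expect_false(mix$synergy_complete)
  expect_true(is.finite(mix$n_co))   # footnote-f route needs only the reference
})

test_that("a missing reference antioxidant leaves R_i unavailable with a warning", {
  x <- one_condition()
  sub <- x$s$traces[c("liposome_pH6_uninhibited", "liposome_pH6_RSV")]
  expect_warning(res <- analyze_experiment(sub, n_boot = 0), "R_i unavailable")
  expect_true(all(is.na(res$R_i)))
  rsv <- res[res$n_compounds == 1L, ]
  expect_true(is.finite(rsv$tau))
  expect_true(is.na(rsv$n))
})

test_that("the metrics table writer emits the summary columns", {
  x <- one_condition()
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(x$res, path)
  lines <- readLines(path)
  expect_true(any(startsWith(lines, "#")))
  hdr <- lines[!startsWith(lines, "#")][1]
  expect_match(hdr, "tau_min")
  expect_match(hdr, "k_inh_M_s")
  expect_match(hdr, "classification")
  body <- read.csv(text = paste(lines[!startsWith(lines, "#")],
                                collapse = "\n"))
  expect_identical(nrow(body), nrow(x$res))
})
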