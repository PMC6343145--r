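test_that("fitting exact points reproduces every published calibration line", {
  cal <- reference_calibration()
  for (i in seq_len(nrow(cal))) {
    x <- exp(seq(log(cal$range_low[i]), log(cal$range_high[i]), length.out = 6))
    y <- cal$slope[i] * x + cal$intercept[i]
    cv <- fit_calibration(x, y, cal$analyte[i])
    expect_equal(cv$slope, cal$slope[i], tolerance = 1e-9)
    expect_equal(cv$intercept, cal$intercept[i], tolerance = 1e-7)
    expect_equal(cv$r, 1.0, tolerance = 1e-9)
    expect_equal(cv$range, c(cal$range_low[i], cal$range_high[i]))
  }
})

test_that("trivial and degenerate calibration fits behave per contract", {
  cv <- fit_calibration(c(0, 1, 2), c(0, 1, 2))
  expect_equal(cv$slope, 1)
  expect_equal(cv$intercept, 0)
  expect_equal(cv$r, 1)
  expect_error(fit_calibration(c(2, 2, 2), c(1, 2, 3)), "singular")
  expect_error(fit_calibration(c(1, 2), c(1, 2)), ">= 3")
})

test_that("OLS slope is unbiased on noisy replicates of a known line", {
  x <- exp(seq(log(0.682), log(33.5), length.out = 6))
  slopes <- vapply(1:1000, function(s) {
    set.seed(s)
    fit_calibration(x, 33.148 * x - 0.7255 + rnorm(6, 0, 0.5))$slope
  }, numeric(1))
  expect_equal(mean(slopes), 33.148, tolerance = 0.005)
})

test_that("calibration inversion recovers known concentrations", {
  cv <- reference_calibration_curves()$hypoxanthine
  expect_equal(invert_calibration(cv, 554.40), 16.747, tolerance = 1e-4)
  expect_equal(invert_calibration(cv, cv$intercept + cv$slope * 0.7), 0.7)
  expect_error(invert_calibration(cv, cv$slope * 50 + cv$intercept),
               class = "dilongqc_range_error")
  expect_warning(
    expect_equal(invert_calibration(cv, cv$slope * 50 + cv$intercept,
                                    allow_extrapolation = TRUE), 50),
    "outside")
  expect_warning(expect_equal(invert_calibration(cv, cv$intercept - 5), 0),
                 "sub-blank")
})

test_that("concentration-to-content applies the 1.0 g / 20 mL preparation", {
  expect_equal(concentration_to_content(16.747, sample_prep()), 334.94)
  expect_equal(concentration_to_content(15.196, sample_prep()), 303.92)
  expect_equal(concentration_to_content(0, sample_prep()), 0)
  expect_equal(concentration_to_content(10, sample_prep(dilution_factor = 3)), 600)
})

test_that("round trip response -> inversion is the identity for every analyte", {
  p0 <- noiseless_params()
  curves <- reference_calibration_curves()
  for (a in nucleoside_analytes()) {
    cv <- curves[[a]]
    for (conc in seq(cv$range[1], cv$range[2], length.out = 7)) {
      area <- response_area(p0, a, conc)
      expect_equal(invert_calibration(cv, area), conc, tolerance = 1e-9)
    }
  }
})

test_that("LOD and LOQ interpolate the S/N series at 3 and 10", {
  expect_warning(
    out3 <- estimate_lod_loq(c(0.5, 1.0, 2.0), c(1.5, 3.0, 6.0)), "bracket")
  expect_equal(unname(out3["lod"]), 1.0)
  expect_true(is.na(out3["loq"]))
  out <- estimate_lod_loq(c(0.05, 0.2, 0.4, 0.8), 30 * c(0.05, 0.2, 0.4, 0.8))
  expect_equal(unname(out["lod"]), 0.1)
  expect_equal(unname(out["loq"]), 1 / 3, tolerance = 1e-9)
  expect_equal(unname(out["loq"] / out["lod"]), 10 / 3, tolerance = 1e-9)
  expect_error(estimate_lod_loq(c(1, 2, 3), c(5, 4, 11)), "increase")
  # scale equivariance: doubling all S/N halves both limits
  half <- estimate_lod_loq(c(0.05, 0.2, 0.4, 0.8), 60 * c(0.05, 0.2, 0.4, 0.8))
  expect_equal(unname(half), unname(out) / 2, tolerance = 1e-12)
})

test_that("batch fixtures quantify back to the published contents exactly", {
  rc <- reference_contents()
  b1 <- rc[rc$batch_id == 1, nucleoside_analytes()]
  q1 <- quantify_batch(peak_table_from_contents(
    stats::setNames(as.numeric(b1), names(b1)), batch_id = "1"))
  expect_equal(q1$content_ug_per_g[q1$analyte == "hypoxanthine"], 334.94)
  expect_identical(q1$flag[q1$analyte == "adenosine"], "nd")
  expect_true(is.na(q1$content_ug_per_g[q1$analyte == "adenosine"]))

  b29 <- rc[rc$batch_id == 29, nucleoside_analytes()]
  q29 <- quantify_batch(peak_table_from_contents(
    stats::setNames(as.numeric(b29), names(b29)), batch_id = "29"))
  expect_equal(q29$content_ug_per_g[q29$analyte == "adenosine"], 303.92)
  # every entry of both batches round-trips exactly
  expect_equal(q1$content_ug_per_g[match(names(b1), q1$analyte)][!is.na(b1)],
               as.numeric(b1)[!is.na(b1)])
  expect_equal(q29$content_ug_per_g[match(names(b29), q29$analyte)],
               as.numeric(b29))
})

test_that("contents above the linear range are diluted and recovered", {
  # batch 21 inosine 2692.14 ug/g implies 134.6 ug/mL, beyond the 83.2 top
  rc <- reference_contents()
  b21 <- rc[rc$batch_id == 21, nucleoside_analytes()]
  tab <- peak_table_from_contents(stats::setNames(as.numeric(b21), names(b21)),
                                  batch_id = "21")
  expect_identical(unname(attr(tab, "dilution")["inosine"]), 2)
  q <- quantify_batch(tab)
  expect_equal(q$content_ug_per_g[q$analyte == "inosine"], 2692.14)
})

test_that("an all-zero chromatogram reports every analyte as not detected", {
  ch <- chromatogram(seq(0, 16, 0.01), rep(0, 1601))
  q <- quantify_batch(assign_analytes(detect_peaks(ch)))
  expect_identical(nrow(q), 6L)
  expect_true(all(q$flag == "nd"))
})

test_that("a detected analyte without a calibration errors", {
  tab <- peak_table_from_contents(c(inosine = 1000), batch_id = "x")
  expect_error(quantify_batch(tab, curves = reference_calibration_curves()["uridine"]),
               "missing calibration")
})
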