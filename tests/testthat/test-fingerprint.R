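mk_table <- function(rts, areas, batch_id) {
  peak_table(data.frame(analyte = NA_character_, apex_rt = rts, height = areas,
                        area = areas, left_bound = rts - 0.2,
                        right_bound = rts + 0.2, snr = Inf),
             batch_id = batch_id)
}

test_that("identical tables give identical common peaks with prevalence 1", {
  tabs <- lapply(c("a", "b", "c"), function(b) mk_table(c(3.2, 9.35), c(5, 50), b))
  cpt <- match_common_peaks(tabs)
  expect_equal(cpt$peaks$mean_rt, c(3.2, 9.35))
  expect_equal(cpt$peaks$prevalence, c(1, 1))
  expect_true(all(cpt$areas[, 2] == 50))
})

test_that("nearby apexes cluster into one common peak at their mean RT", {
  cpt <- match_common_peaks(list(mk_table(9.35, 10, "A"), mk_table(9.41, 12, "B")),
                            rt_tolerance = 0.1)
  expect_identical(nrow(cpt$peaks), 1L)
  expect_equal(cpt$peaks$mean_rt, 9.38)
  expect_equal(cpt$peaks$prevalence, 1)
})

test_that("apexes separated beyond tolerance stay distinct, absent batches get area 0", {
  cpt <- match_common_peaks(list(mk_table(c(3.2, 9.35), c(5, 10), "A"),
                                 mk_table(9.35, 12, "B")), rt_tolerance = 0.1)
  expect_identical(nrow(cpt$peaks), 2L)
  expect_equal(cpt$peaks$prevalence, c(0.5, 1))
  expect_equal(unname(cpt$areas["B", 1]), 0)
  expect_error(match_common_peaks(list()), "empty")
})

test_that("the 22 authentic batches share all five nucleoside peaks", {
  st <- study_fixture(42)
  auth <- which(st$manifest$role == "authentic")
  cpt <- match_common_peaks(st$tables[auth])
  expect_identical(nrow(cpt$peaks), 5L)
  expect_true(all(cpt$peaks$prevalence == 1))
  expect_equal(cpt$peaks$mean_rt,
               unname(analyte_retention_times()[1:5]), tolerance = 0.02)
})

test_that("reference selection picks the inosine peak at 9.35 min", {
  st <- study_fixture(42)
  auth <- which(st$manifest$role == "authentic")
  cpt <- match_common_peaks(st$tables[auth])
  ref <- select_reference_peak(cpt)
  expect_equal(cpt$peaks$mean_rt[ref], 9.35, tolerance = 0.05)
  expect_identical(select_reference_peak(cpt, "fixed-rt:9.35"), ref)
})

test_that("a single common peak is its own reference; no ubiquitous peak errors", {
  one <- match_common_peaks(list(mk_table(9.35, 10, "A"), mk_table(9.36, 11, "B")))
  expect_identical(select_reference_peak(one), 1L)
  none <- match_common_peaks(list(mk_table(3.2, 10, "A"), mk_table(9.35, 11, "B")))
  expect_error(select_reference_peak(none), "reference")
})

test_that("relative metrics are ratios to the reference peak", {
  cpt <- match_common_peaks(list(mk_table(c(3.20, 9.35), c(50, 100), "A"),
                                 mk_table(c(3.20, 9.35), c(25, 100), "B")))
  cpt <- relative_metrics(cpt, 2L)
  expect_true(all(cpt$rrt[, 2] == 1))
  expect_true(all(cpt$rpa[, 2] == 1))
  expect_equal(unname(cpt$rrt[, 1]), rep(3.20 / 9.35, 2))
  expect_equal(unname(cpt$rpa[, 1]), c(0.5, 0.25))
})

test_that("zero reference area errors naming the batch", {
  cpt <- match_common_peaks(list(mk_table(c(3.20, 9.35), c(50, 100), "A"),
                                 mk_table(3.20, 25, "Bbad")))
  expect_error(relative_metrics(cpt, 2L), "Bbad")
})

test_that("mean fusion is the pointwise average with k-copy weighting", {
  a <- gauss_chromatogram(10, 0.05, mu = 3.2, batch_id = "a")
  b <- gauss_chromatogram(30, 0.05, mu = 9.35, batch_id = "b")
  expect_equal(mean_fusion(list(a, a))$intensity, a$intensity)
  m2 <- mean_fusion(list(a, b))
  idx <- c(1, 321, 936, 1200, 1601)
  expect_equal(m2$intensity[idx], ((a$intensity + b$intensity) / 2)[idx])
  m6 <- mean_fusion(list(a, a, a, b, b, b))
  expect_equal(m6$intensity, m2$intensity)
  short <- chromatogram(seq(0, 8, 0.01), rep(1, 801))
  expect_error(mean_fusion(list(a, short)), "grid")
})

test_that("similarity matches closed-form Pearson and is scale invariant", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(similarity(x, c(2, 4, 6, 8, 10)), 1.0)
  expect_equal(similarity(x, c(5, 4, 3, 2, 1)), -1.0)
  a <- gauss_chromatogram(10, 0.05, mu = 3.2)
  expect_equal(similarity(a, a), 1.0)
  expect_equal(similarity(a, 2 * a$intensity), 1.0)
  expect_error(similarity(rep(1, 5), x), "zero-variance")
})

test_that("Pearson similarity equals a brute-force covariance computation", {
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(50); y <- rnorm(50)
    brute <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(similarity(x, y), brute, tolerance = 1e-12)
    expect_equal(similarity(x, y, method = "cosine"),
                 sum(x * y) / sqrt(sum(x^2) * sum(y^2)), tolerance = 1e-12)
  }
})

test_that("characteristic peaks follow the prevalence threshold", {
  st <- study_fixture(42)
  auth <- which(st$manifest$role == "authentic")
  expect_length(characteristic_peaks(match_common_peaks(st$tables[auth])), 5L)
  mm <- which(st$manifest$species == "Metaphire magna")
  expect_length(characteristic_peaks(match_common_peaks(st$tables[mm])), 6L)
  ao <- which(st$manifest$species == "Amynthas obscuritoporus")
  expect_length(characteristic_peaks(match_common_peaks(st$tables[ao])), 6L)
  # threshold 1.0 excludes a peak missing from one batch
  cpt <- match_common_peaks(list(mk_table(c(3.2, 9.35), c(5, 10), "A"),
                                 mk_table(9.35, 12, "B")))
  expect_identical(characteristic_peaks(cpt, 1.0), 2L)
})

test_that("batch order never changes common peaks, fusion or similarity", {
  st <- study_fixture(42)
  auth <- which(st$manifest$role == "authentic")
  perm <- rev(auth)
  c1 <- match_common_peaks(st$tables[auth])
  c2 <- match_common_peaks(st$tables[perm])
  expect_equal(c1$peaks, c2$peaks)
  expect_equal(c1$areas[order(rownames(c1$areas)), ],
               c2$areas[order(rownames(c2$areas)), ])
  m1 <- mean_fusion(st$corrected[auth])
  m2 <- mean_fusion(st$corrected[perm])
  expect_equal(m1$intensity, m2$intensity)
  expect_equal(similarity(st$corrected[[3]], m1), similarity(st$corrected[[3]], m2))
})

test_that("authentic batches stay above the similarity floor across seeds", {
  mins <- vapply(1:20, function(s) {
    st <- generate_study(default_study_design(s))
    auth <- which(st$manifest$role == "authentic")
    corr <- lapply(st$chromatograms[auth], correct_baseline)
    mv <- mean_fusion(corr)
    min(vapply(corr, similarity, numeric(1), mean_vector = mv))
  }, numeric(1))
  expect_gte(sum(mins >= 0.811), 19L)
  # every batch is far more similar to the consensus than pure noise is
  st <- study_fixture(42)
  auth <- which(st$manifest$role == "authentic")
  mv <- mean_fusion(st$corrected[auth])
  noise <- correct_baseline(generate_chromatogram(c(inosine = 0),
                                                  generator_params(), seed = 1))
  expect_lt(similarity(noise, mv), min(mins))
})
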