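test_that("zero concentrations with zero noise give a flat zero trace", {
  ch <- generate_chromatogram(
    stats::setNames(rep(0, 6), nucleoside_analytes()),
    noiseless_params(), seed = 1)
  expect_true(all(ch$intensity == 0))
})

test_that("integrated trace area matches the linear response model", {
  p0 <- noiseless_params()
  for (a in c("hypoxanthine", "inosine", "adenosine")) {
    for (conc in c(2, 10, 30)) {
      ch <- generate_chromatogram(stats::setNames(conc, a), p0, seed = 1)
      got <- sum(diff(ch$time) * (ch$intensity[-1] + ch$intensity[-length(ch$intensity)]) / 2)
      expect_equal(got, response_area(p0, a, conc), tolerance = 1e-3)
    }
  }
})

test_that("the same seed reproduces traces bit-identically", {
  p <- generator_params()
  conc <- mid_concentrations()
  a <- generate_chromatogram(conc, p, seed = 99)
  b <- generate_chromatogram(conc, p, seed = 99)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(
    generate_chromatogram(conc, p, seed = 100)$intensity, a$intensity))
})

test_that("negative concentrations are rejected naming the analyte", {
  expect_error(generate_chromatogram(c(uridine = -1), noiseless_params()),
               "uridine")
})

test_that("increasing a concentration never decreases its integrated area", {
  p0 <- noiseless_params()
  concs <- c(1, 2, 5, 10, 20, 33)
  areas <- vapply(concs, function(cc) {
    ch <- generate_chromatogram(c(hypoxanthine = cc), p0)
    sum(ch$intensity) * 0.01
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("the default study has 42 batches, 22 authentic, no authentic adenosine", {
  st <- study_fixture(42)
  expect_length(st$chromatograms, 42L)
  expect_identical(sum(st$manifest$role == "authentic"), 22L)
  gt_auth <- subset(st$ground_truth, species == "Pheretima aspergillum" &
                      analyte == "adenosine")
  expect_identical(nrow(gt_auth), 22L)
  expect_true(all(gt_auth$content_ug_per_g == 0))
  ade_adult <- subset(st$ground_truth, species != "Pheretima aspergillum" &
                        analyte == "adenosine")
  expect_true(all(ade_adult$content_ug_per_g > 0))
})

test_that("ground truth respects profile ranges and the dilution invariant", {
  st <- study_fixture(42)
  profs <- species_profiles()
  gt <- st$ground_truth
  for (i in seq_len(nrow(gt))) {
    rng <- profs[[gt$species[i]]]$analyte_content_ranges[, gt$analyte[i]]
    expect_gte(gt$content_ug_per_g[i], rng[1])
    expect_lte(gt$content_ug_per_g[i], rng[2])
  }
  # concentration = content * mass / volume / dilution (1.0 g, 20 mL prep)
  expect_equal(gt$concentration_ug_per_ml,
               gt$content_ug_per_g * 1.0 / 20 / gt$dilution_factor)
  expect_true(all(gt$dilution_factor >= 1 &
                    gt$dilution_factor == round(gt$dilution_factor)))
})

test_that("study generation is reproducible under a fixed seed", {
  d <- study_design(batch_id = 1:4,
                    species = c(rep("Pheretima aspergillum", 2),
                                rep("Metaphire magna", 2)), seed = 7)
  a <- generate_study(d)
  b <- generate_study(d)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$chromatograms[[3]]$intensity, b$chromatograms[[3]]$intensity)
})

test_that("missing species profile errors naming the batch", {
  d <- study_design(batch_id = c("x1", "x2"),
                    species = c("Pheretima aspergillum", "Lumbricus terrestris"))
  expect_error(generate_study(d), "x2")
})

test_that("standard series span the range geometrically", {
  std <- generate_standards(list(hypoxanthine = c(0.682, 33.5)), n_levels = 6,
                            params = noiseless_params(), seed = 1)
  conc <- std$concentrations$hypoxanthine
  expect_equal(conc[1], 0.682)
  expect_equal(conc[6], 33.5)
  ratios <- conc[-1] / conc[-6]
  expect_equal(ratios, rep(ratios[1], 5))
  expect_length(std$chromatograms, 6L)

  two <- generate_standards(list(inosine = c(1.66, 83.2)), n_levels = 2,
                            params = noiseless_params())
  expect_equal(two$concentrations$inosine, c(1.66, 83.2))
  expect_error(generate_standards(list(inosine = c(0, 5)), 6), "range")
  expect_error(generate_standards(list(inosine = c(5, 2)), 6), "range")
})

test_that("spike experiments emit one unspiked and n spiked replicate traces", {
  base <- mid_concentrations() / 2
  sp <- generate_spike_experiment(base, base, n_replicates = 3,
                                  params = generator_params(), seed = 5)
  expect_length(sp$spiked, 3L)
  expect_s3_class(sp$unspiked, "chromatogram")
  expect_equal(sp$truth$total_conc, sp$truth$original_conc + sp$truth$spike_conc)
  sp2 <- generate_spike_experiment(base, base, n_replicates = 3,
                                   params = generator_params(), seed = 5)
  expect_identical(sp$spiked[[2]]$intensity, sp2$spiked[[2]]$intensity)
  expect_error(generate_spike_experiment(base, -base), "positive")
})

test_that("species profiles encode adenosine absence in the authentic species", {
  profs <- species_profiles()
  pa <- profs[["Pheretima aspergillum"]]
  expect_false(pa$adenosine_present)
  expect_equal(unname(pa$analyte_content_ranges[, "adenosine"]), c(0, 0))
  for (s in c("Amynthas obscuritoporus", "Metaphire magna")) {
    expect_true(profs[[s]]$adenosine_present)
    expect_true(all(profs[[s]]$analyte_content_ranges[, "adenosine"] > 0))
  }
})

test_that("simulated authentic batches never show an adenosine peak, adulterants always do", {
  st <- study_fixture(42)
  for (i in seq_along(st$tables)) {
    has_ade <- "adenosine" %in% st$tables[[i]]$analyte
    expect_identical(has_ade, st$manifest$role[i] == "adulterant")
  }
})
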