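# Shared fixtures, memoized so expensive simulations run once per suite.

.fixtures <- new.env(parent = emptyenv())

# default-parameter 42-batch study plus its corrected traces and peak tables
study_fixture <- function(seed = 42L) {
  key <- paste0("study_", seed)
  if (is.null(.fixtures[[key]])) {
    st <- generate_study(default_study_design(seed))
    st$corrected <- lapply(st$chromatograms, correct_baseline)
    st$tables <- lapply(st$corrected, function(ch)
      assign_analytes(detect_peaks(ch, min_snr = 3)))
    .fixtures[[key]] <- st
  }
  .fixtures[[key]]
}

# a bare Gaussian trace built directly (independent of the generator)
gauss_chromatogram <- function(height, sigma, mu = 9.35, extra = 0,
                               grid = seq(0, 16, 0.01), batch_id = "gauss") {
  chromatogram(grid, height * exp(-(grid - mu)^2 / (2 * sigma^2)) + extra,
               batch_id = batch_id)
}

# midpoints of the published linear ranges, named per analyte
mid_concentrations <- function() {
  cal <- reference_calibration()
  stats::setNames((cal$range_low + cal$range_high) / 2, cal$analyte)
}

table2_ranges <- function() {
  cal <- reference_calibration()
  stats::setNames(lapply(seq_len(nrow(cal)),
                         function(i) c(cal$range_low[i], cal$range_high[i])),
                  cal$analyte)
}
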