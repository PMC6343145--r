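#' Generator parameters for synthetic chromatograms
#'
#' Defines the simulated instrument: analyte retention times, Gaussian peak
#' width, the linear area response per analyte, baseline noise, slow drift,
#' retention-time jitter and the acquisition grid. Defaults reproduce the
#' reference instrument: the published calibration lines are reused as the
#' true area response (so quantitation round-trips exactly), peaks are
#' symmetric Gaussians of width 0.05 min, the grid is 0--16 min at 0.01 min,
#' baseline noise is 0.05 mAU, drift a single 0.2 mAU sinusoid and
#' retention-time jitter 0.01 min (1 s) per batch.
#'
#' @param analyte_rts Named retention times (min), strictly increasing.
#' @param peak_sigma Gaussian peak width sigma (min), > 0.
#' @param response Named list per analyte of `c(slope, intercept)`:
#'   peak area (mAU·min) = slope x concentration (µg/mL) + intercept.
#' @param noise_sd White baseline noise standard deviation (mAU).
#' @param drift_amplitude Amplitude (mAU) of a single slow sinusoidal
#'   baseline drift; phase is drawn per trace.
#' @param rt_jitter_sd Per-trace retention-time jitter sd (min).
#' @param grid `c(t_start, t_end, step)` in min.
#' @return A `generator_params` object.
#' @export
generator_params <- function(analyte_rts = analyte_retention_times(),
                             peak_sigma = 0.05,
                             response = NULL,
                             noise_sd = 0.05,
                             drift_amplitude = 0.2,
                             rt_jitter_sd = 0.01,
                             grid = c(0, 16, 0.01)) {
  if (is.null(response)) {
    cal <- reference_calibration()
    response <- stats::setNames(
      lapply(seq_len(nrow(cal)), function(i) c(slope = cal$slope[i], intercept = cal$intercept[i])),
      cal$analyte)
    response <- response[names(analyte_rts)[names(analyte_rts) %in% names(response)]]
  }
  stopifnot(length(grid) == 3L, grid[3L] > 0, grid[1L] < grid[2L],
            peak_sigma > 0, noise_sd >= 0, drift_amplitude >= 0, rt_jitter_sd >= 0)
  if (is.null(names(analyte_rts)) || anyNA(names(analyte_rts)))
    stop("analyte_rts must be a named vector")
  if (any(diff(analyte_rts) <= 0))
    stop("analyte_rts must be strictly increasing in elution order")
  if (any(analyte_rts < grid[1L] | analyte_rts > grid[2L]))
    stop("all analyte_rts must lie within the grid")
  if (!all(names(analyte_rts) %in% names(response)))
    stop("response must cover every analyte in analyte_rts")
  structure(list(analyte_rts = analyte_rts, peak_sigma = peak_sigma,
                 response = response, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude, rt_jitter_sd = rt_jitter_sd,
                 grid = grid),
            class = "generator_params")
}

#' Noise-free generator parameters
#'
#' Convenience wrapper: [generator_params()] with noise, drift and
#' retention-time jitter all zero, for analytic fixtures.
#'
#' @param ... Passed on to [generator_params()].
#' @export
noiseless_params <- function(...) {
  generator_params(noise_sd = 0, drift_amplitude = 0, rt_jitter_sd = 0, ...)
}

#' True peak area under the simulated response model
#'
#' Area (mAU·min) = slope x concentration + intercept, clipped at zero; a
#' concentration of exactly zero means the analyte is absent (area 0).
#'
#' @param params A [generator_params] object.
#' @param analyte Analyte name.
#' @param concentration Concentration (µg/mL), >= 0.
#' @return Numeric area (mAU·min).
#' @export
response_area <- function(params, analyte, concentration) {
  r <- params$response[[analyte]]
  if (is.null(r)) stop("no response model for analyte: ", analyte)
  ifelse(concentration == 0, 0,
         pmax(0, r[["slope"]] * concentration + r[["intercept"]]))
}

#' Simulate one chromatogram
#'
#' The trace is a sum of symmetric Gaussian peaks (one per analyte with
#' non-zero concentration, apex at the jittered retention time, area from the
#' linear response model), a slow sinusoidal baseline drift with random
#' phase, and white Gaussian noise. With the same inputs and seed the trace
#' is bit-identical across calls.
#'
#' @param concentrations Named concentrations (µg/mL) of the injected
#'   solution; names must be analytes known to `params`. Zero means absent.
#' @param params A [generator_params] object.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param batch_id Batch label for the trace.
#' @return A [chromatogram].
#' @export
generate_chromatogram <- function(concentrations, params = generator_params(),
                                  seed = NULL, batch_id = NA_character_) {
  stopifnot(inherits(params, "generator_params"))
  if (is.null(names(concentrations)))
    stop("concentrations must be a named vector")
  bad <- names(concentrations)[!(names(concentrations) %in% names(params$analyte_rts))]
  if (length(bad)) stop("unknown analyte(s): ", paste(bad, collapse = ", "))
  neg <- names(concentrations)[concentrations < 0]
  if (length(neg))
    stop("negative concentration for analyte(s): ", paste(neg, collapse = ", "))
  tg <- seq(params$grid[1L], params$grid[2L], by = params$grid[3L])
  n <- length(tg)
  analytes <- names(params$analyte_rts)
  conc <- stats::setNames(numeric(length(analytes)), analytes)
  conc[names(concentrations)] <- concentrations
  with_seed(seed, {
    jitter <- stats::rnorm(length(analytes), 0, params$rt_jitter_sd)
    phase <- stats::runif(1L, 0, 2 * pi)
    noise <- stats::rnorm(n, 0, params$noise_sd)
    y <- numeric(n)
    for (i in seq_along(analytes)) {
      a <- analytes[i]
      area <- response_area(params, a, conc[[a]])
      if (area > 0) {
        h <- area / (params$peak_sigma * sqrt(2 * pi))
        mu <- params$analyte_rts[[a]] + jitter[i]
        y <- y + h * exp(-(tg - mu)^2 / (2 * params$peak_sigma^2))
      }
    }
    drift <- params$drift_amplitude *
      sin(2 * pi * (tg - params$grid[1L]) / diff(params$grid[1:2]) + phase)
    chromatogram(tg, y + drift + noise, batch_id = batch_id)
  })
}

# smallest integer dilution bringing conc inside [, high]; 1 if already in
auto_dilution <- function(conc, high) {
  ifelse(conc > high, ceiling(conc / high), 1)
}

#' Simulate a multi-batch authentication study
#'
#' For each batch in the design, nucleoside contents are sampled
#' log-uniformly within the species profile ranges, converted to extract
#' concentrations through the sample preparation (default 1.0 g in 20 mL),
#' diluted by the smallest integer factor whenever a concentration exceeds
#' the analyte's linear range, and rendered as a chromatogram.
#'
#' @param design A [study_design].
#' @param profiles Named list of [species_profile] objects covering every
#'   species in the design.
#' @param params A [generator_params].
#' @param prep A [sample_prep]; default 1.0 g in 20 mL.
#' @param seed Master seed; defaults to `design$seed`.
#' @return List with `chromatograms` (one [chromatogram] per batch),
#'   `ground_truth` (long data frame: batch_id, species, analyte,
#'   content_ug_per_g, concentration_ug_per_ml, dilution_factor) and
#'   `manifest` (batch_id, species, role, file, dilution_factor).
#' @export
generate_study <- function(design, profiles = species_profiles(),
                           params = generator_params(),
                           prep = sample_prep(), seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  seed <- seed %||% design$seed
  batches <- design$batches
  missing_prof <- !(batches$species %in% names(profiles))
  if (any(missing_prof))
    stop("no species profile for batch(es): ",
         paste(batches$batch_id[missing_prof], collapse = ", "))
  analytes <- names(params$analyte_rts)
  cal <- reference_calibration()
  hi_range <- stats::setNames(cal$range_high, cal$analyte)[analytes]
  nb <- nrow(batches)
  with_seed(seed, {
    truth <- vector("list", nb)
    chroms <- vector("list", nb)
    batch_seeds <- sample.int(.Machine$integer.max - 1L, nb)
    for (b in seq_len(nb)) {
      prof <- profiles[[batches$species[b]]]
      rng <- prof$analyte_content_ranges[, analytes, drop = FALSE]
      content <- vapply(seq_along(analytes), function(i) {
        lo <- rng[1L, i]; hi <- rng[2L, i]
        if (hi == 0) 0
        else if (lo == hi) lo
        else exp(stats::runif(1L, log(lo), log(hi)))
      }, numeric(1L))
      names(content) <- analytes
      conc0 <- content * prep$mass / prep$volume
      dil <- auto_dilution(conc0, hi_range)
      conc <- conc0 / dil
      chroms[[b]] <- generate_chromatogram(conc, params, seed = batch_seeds[b],
                                           batch_id = as.character(batches$batch_id[b]))
      truth[[b]] <- data.frame(batch_id = batches$batch_id[b],
                               species = batches$species[b],
                               analyte = analytes,
                               content_ug_per_g = unname(content),
                               concentration_ug_per_ml = unname(conc),
                               dilution_factor = unname(dil),
                               stringsAsFactors = FALSE)
    }
    manifest <- data.frame(
      batch_id = batches$batch_id, species = batches$species, role = batches$role,
      file = sprintf("batch_%s.csv", batches$batch_id),
      dilution_factor = vapply(truth, function(d) paste(d$dilution_factor, collapse = ";"), ""),
      stringsAsFactors = FALSE)
    list(chromatograms = chroms,
         ground_truth = do.call(rbind, truth),
         manifest = manifest)
  })
}

#' Simulate a calibration standard series
#'
#' `generate_standards()` builds a geometric dilution series per analyte
#' spanning `[low, high]` and renders one mixed-standard chromatogram per
#' level. `simulate_standard_areas()` skips the trace and returns the true
#' response areas with optional multiplicative Gaussian noise, the input the
#' calibration fit consumes.
#'
#' @param ranges Named list (or 2-row matrix) of `c(low, high)` concentration
#'   ranges (µg/mL) per analyte; 0 < low < high.
#' @param n_levels Number of levels, >= 2; levels are spaced geometrically
#'   and include both endpoints.
#' @param params A [generator_params].
#' @param seed Optional integer seed.
#' @return `generate_standards()`: list with `chromatograms` (one per level)
#'   and `concentrations` (data frame level x analyte).
#' @export
generate_standards <- function(ranges, n_levels = 6L, params = generator_params(),
                               seed = NULL) {
  conc <- standard_levels(ranges, n_levels)
  chroms <- with_seed(seed, {
    level_seeds <- sample.int(.Machine$integer.max - 1L, n_levels)
    lapply(seq_len(n_levels), function(l) {
      v <- unlist(conc[l, setdiff(names(conc), "level"), drop = FALSE])
      generate_chromatogram(v, params, seed = level_seeds[l],
                            batch_id = sprintf("std_L%d", l))
    })
  })
  list(chromatograms = chroms, concentrations = conc)
}

standard_levels <- function(ranges, n_levels) {
  if (is.matrix(ranges)) ranges <- as.list(as.data.frame(ranges))
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be >= 2")
  cols <- lapply(names(ranges), function(a) {
    lo <- ranges[[a]][1L]; hi <- ranges[[a]][2L]
    if (!(lo > 0) || !(lo < hi))
      stop("invalid range for ", a, ": need 0 < low < high")
    exp(seq(log(lo), log(hi), length.out = n_levels))
  })
  out <- data.frame(level = seq_len(n_levels))
  out[names(ranges)] <- cols
  out
}

#' @rdname generate_standards
#' @param rel_noise Relative (multiplicative) Gaussian area noise, e.g.
#'   0.001 for 0.1%.
#' @return `simulate_standard_areas()`: long data frame `analyte`, `level`,
#'   `concentration`, `area`.
#' @export
simulate_standard_areas <- function(ranges, n_levels = 6L, rel_noise = 0.001,
                                    params = generator_params(), seed = NULL) {
  conc <- standard_levels(ranges, n_levels)
  analytes <- setdiff(names(conc), "level")
  out <- do.call(rbind, lapply(analytes, function(a) {
    data.frame(analyte = a, level = conc$level, concentration = conc[[a]],
               area = response_area(params, a, conc[[a]]),
               stringsAsFactors = FALSE)
  }))
  with_seed(seed, {
    out$area <- out$area * (1 + stats::rnorm(nrow(out), 0, rel_noise))
  })
  out
}

#' Simulate a standard-addition (spike) recovery experiment
#'
#' Generates one unspiked trace of the base solution and `n_replicates`
#' spiked traces at base + spike concentrations. Where a spiked total
#' exceeds an analyte's linear range, the smallest integer dilution is
#' applied and recorded, mirroring the study generator.
#'
#' @param base_concentrations Named base (sample) concentrations, µg/mL.
#' @param spike_amounts Named spiked concentrations added, µg/mL; > 0.
#' @param n_replicates Number of spiked replicates, >= 1.
#' @param params A [generator_params].
#' @param seed Optional integer seed.
#' @return List with `unspiked` ([chromatogram]), `spiked` (list of
#'   chromatograms) and `truth` (data frame: analyte, original, spike and
#'   total concentration, dilution factors for both solutions).
#' @export
generate_spike_experiment <- function(base_concentrations, spike_amounts,
                                      n_replicates = 3L,
                                      params = generator_params(), seed = NULL) {
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (any(spike_amounts <= 0)) stop("spike_amounts must be positive")
  analytes <- names(params$analyte_rts)
  base <- stats::setNames(numeric(length(analytes)), analytes)
  base[names(base_concentrations)] <- base_concentrations
  spike <- stats::setNames(numeric(length(analytes)), analytes)
  spike[names(spike_amounts)] <- spike_amounts
  total <- base + spike
  cal <- reference_calibration()
  hi <- stats::setNames(cal$range_high, cal$analyte)[analytes]
  dil_base <- auto_dilution(base, hi)
  dil_total <- auto_dilution(total, hi)
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n_replicates + 1L)
    unspiked <- generate_chromatogram(base / dil_base, params, seed = seeds[1L],
                                      batch_id = "unspiked")
    spiked <- lapply(seq_len(n_replicates), function(r) {
      generate_chromatogram(total / dil_total, params, seed = seeds[r + 1L],
                            batch_id = sprintf("spiked_%d", r))
    })
    list(unspiked = unspiked, spiked = spiked,
         truth = data.frame(analyte = analytes,
                            original_conc = unname(base),
                            spike_conc = unname(spike),
                            total_conc = unname(total),
                            dilution_unspiked = unname(dil_base),
                            dilution_spiked = unname(dil_total),
                            stringsAsFactors = FALSE))
  })
}

#' Exact forward-model peak table for known contents
#'
#' Builds the peak table a perfect measurement of the given contents would
#' produce: extract concentrations through the sample preparation, automatic
#' integer dilution into the linear range, and areas from the calibration
#' lines applied forward. Used for exact quantitation round-trip fixtures.
#'
#' @param contents Named contents (µg/g); `NA` or 0 means absent.
#' @param batch_id Batch label.
#' @param curves Named list of [calibration_curve] objects.
#' @param prep A [sample_prep].
#' @param params A [generator_params] (retention times and peak width).
#' @return A peak table (see [detect_peaks()]) with an attached
#'   `dilution` attribute (named per-analyte factors).
#' @export
peak_table_from_contents <- function(contents, batch_id = NA_character_,
                                     curves = reference_calibration_curves(),
                                     prep = sample_prep(),
                                     params = generator_params()) {
  analytes <- names(params$analyte_rts)
  cont <- stats::setNames(numeric(length(analytes)), analytes)
  present <- intersect(names(contents), analytes)
  cont[present] <- ifelse(is.na(contents[present]), 0, contents[present])
  conc0 <- cont * prep$mass / prep$volume
  hi <- vapply(curves[analytes], function(cv) cv$range[2L], numeric(1L))
  dil <- auto_dilution(conc0, hi)
  conc <- conc0 / dil
  rows <- lapply(analytes, function(a) {
    if (conc[[a]] == 0) return(NULL)
    cv <- curves[[a]]
    area <- cv$slope * conc[[a]] + cv$intercept
    rt <- params$analyte_rts[[a]]
    data.frame(analyte = a, apex_rt = rt,
               height = area / (params$peak_sigma * sqrt(2 * pi)), area = area,
               left_bound = rt - 4 * params$peak_sigma,
               right_bound = rt + 4 * params$peak_sigma,
               snr = Inf, stringsAsFactors = FALSE)
  })
  tab <- peak_table(do.call(rbind, rows), batch_id = batch_id)
  attr(tab, "dilution") <- dil
  tab
}
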