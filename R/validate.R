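#' Relative standard deviation
#'
#' 100 x sample standard deviation (n - 1 denominator) / mean.
#'
#' @param values At least two measurements with non-zero mean.
#' @return RSD in percent.
#' @export
rsd <- function(values) {
  stopifnot(length(values) >= 2L)
  m <- mean(values)
  if (m == 0) stop("zero mean: RSD undefined")
  100 * stats::sd(values) / m
}

#' Standard-addition recovery
#'
#' recovery (%) = (amount found - original amount) / amount spiked x 100.
#'
#' @param found_total Total amount found in the spiked sample (µg).
#' @param original Amount in the unspiked sample (µg).
#' @param spiked Amount spiked (µg), > 0.
#' @return Recovery in percent.
#' @export
recovery <- function(found_total, original, spiked) {
  if (any(spiked <= 0)) stop("spiked amount must be positive")
  (found_total - original) / spiked * 100
}

#' Replicate design for method validation
#'
#' Defaults follow the standard protocol: intra-day precision from six
#' replicate injections, inter-day precision over three consecutive days,
#' repeatability from six preparations of one sample, stability at five time
#' points (0--4 h), and recovery from three spiked replicates.
#'
#' @param intra_n,inter_days,inter_n,repeatability_n,stability_points,recovery_n
#'   Replicate counts; all must be >= 2 (days >= 2).
#' @return A `validation_protocol` list.
#' @export
validation_protocol <- function(intra_n = 6L, inter_days = 3L, inter_n = 6L,
                                repeatability_n = 6L, stability_points = 5L,
                                recovery_n = 3L) {
  p <- list(intra_n = intra_n, inter_days = inter_days, inter_n = inter_n,
            repeatability_n = repeatability_n, stability_points = stability_points,
            recovery_n = recovery_n)
  if (any(unlist(p) < 2L)) stop("every replicate count must be >= 2")
  structure(p, class = "validation_protocol")
}

#' Run a simulated analytical validation
#'
#' Simulates each validation experiment with the chromatogram generator,
#' quantifies every trace through the full signal pipeline (baseline
#' correction, peak detection, analyte assignment, calibration inversion),
#' and aggregates per-analyte statistics: intra-/inter-day precision RSDs of
#' peak areas, repeatability and stability RSDs, and standard-addition
#' recovery (spike equal to the sample's own amount).
#'
#' The default sample is reference batch 23, the adulterant batch used for
#' repeatability, stability and recovery in the reference protocol; all six
#' analytes are present and within their linear ranges.
#'
#' @param protocol A [validation_protocol].
#' @param params A [generator_params].
#' @param seed Integer seed.
#' @param sample_contents Named true contents (µg/g) of the validation
#'   sample; default reference batch 23.
#' @param curves Named list of [calibration_curve] objects.
#' @param prep A [sample_prep].
#' @return A `validation_report` data frame (analyte, intra_day_rsd,
#'   inter_day_rsd, repeatability_rsd, stability_rsd, recovery_mean,
#'   recovery_rsd, all in %), with attributes `protocol` and
#'   `grand_mean_recovery` (mean over all analyte x replicate recoveries).
#' @export
run_validation <- function(protocol = validation_protocol(),
                           params = generator_params(), seed = 1L,
                           sample_contents = NULL,
                           curves = reference_calibration_curves(),
                           prep = sample_prep()) {
  stopifnot(inherits(protocol, "validation_protocol"))
  if (is.null(sample_contents)) {
    rc <- reference_contents()
    row <- rc[rc$batch_id == 23L, nucleoside_analytes()]
    sample_contents <- stats::setNames(as.numeric(row[1L, ]), names(row))
  }
  analytes <- names(params$analyte_rts)
  cont <- stats::setNames(numeric(length(analytes)), analytes)
  keep <- intersect(names(sample_contents), analytes)
  cont[keep] <- ifelse(is.na(sample_contents[keep]), 0, sample_contents[keep])
  conc0 <- cont * prep$mass / prep$volume
  hi <- vapply(curves[analytes], function(cv) cv$range[2L], numeric(1L))
  dil <- auto_dilution(conc0, hi)
  conc <- conc0 / dil

  measure_areas <- function(s) {
    ch <- generate_chromatogram(conc, params, seed = s, batch_id = "validation")
    q <- measure_batch(ch, curves, prep, dilution = dil, min_snr = 3)
    stats::setNames(q$area, q$analyte)[analytes]
  }
  measure_contents <- function(ch, d) {
    q <- measure_batch(ch, curves, prep, dilution = d, min_snr = 3)
    stats::setNames(q$content_ug_per_g, q$analyte)[analytes]
  }

  with_seed(seed, {
    n_seeds <- with(protocol, intra_n + inter_days * inter_n + repeatability_n +
                      stability_points + 1L)
    seeds <- sample.int(.Machine$integer.max - 1L, n_seeds)
    si <- 0L
    take <- function(k) { out <- seeds[si + seq_len(k)]; si <<- si + k; out }

    intra <- sapply(take(protocol$intra_n), measure_areas)
    inter_daymeans <- sapply(seq_len(protocol$inter_days), function(d)
      rowMeans(sapply(take(protocol$inter_n), measure_areas)))
    repeatability <- sapply(take(protocol$repeatability_n), measure_areas)
    stability <- sapply(take(protocol$stability_points), measure_areas)

    spike <- generate_spike_experiment(conc * dil, conc * dil,
                                       n_replicates = protocol$recovery_n,
                                       params = params, seed = take(1L))
    original_amt <- measure_contents(spike$unspiked,
                                     stats::setNames(spike$truth$dilution_unspiked,
                                                     spike$truth$analyte)) * prep$mass
    spike_amt <- stats::setNames(spike$truth$spike_conc * prep$volume,
                                 spike$truth$analyte)[analytes]
    rec <- sapply(spike$spiked, function(ch) {
      found <- measure_contents(ch, stats::setNames(spike$truth$dilution_spiked,
                                                    spike$truth$analyte)) * prep$mass
      recovery(found, original_amt, spike_amt)
    })

    report <- data.frame(
      analyte = analytes,
      intra_day_rsd = apply(intra, 1L, rsd),
      inter_day_rsd = apply(inter_daymeans, 1L, rsd),
      repeatability_rsd = apply(repeatability, 1L, rsd),
      stability_rsd = apply(stability, 1L, rsd),
      recovery_mean = rowMeans(rec),
      recovery_rsd = apply(rec, 1L, function(v) 100 * stats::sd(v) / mean(v)),
      stringsAsFactors = FALSE, row.names = NULL)
    structure(report,
              class = c("validation_report", "data.frame"),
              protocol = protocol,
              grand_mean_recovery = mean(rec))
  })
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report (RSD %, recovery %):\n")
  print.data.frame(x, digits = 4)
  cat(sprintf("Grand mean recovery: %.2f%%\n", attr(x, "grand_mean_recovery")))
  invisible(x)
}

#' @rdname run_validation
#' @param report A `validation_report`.
#' @param path Output CSV path.
#' @export
write_validation_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
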