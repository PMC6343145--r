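#' Calibration curve
#'
#' Linear area response of one analyte: peak area (mAU·min) =
#' `slope` x concentration (µg/mL) + `intercept`, with the Pearson
#' correlation coefficient of the calibration points, the linear range, and
#' optionally LOD/LOQ (the concentrations giving S/N 3 and 10).
#'
#' @param analyte Analyte label.
#' @param slope Slope (mAU·min per µg/mL), > 0.
#' @param intercept Intercept (mAU·min).
#' @param r Correlation coefficient in `[-1, 1]`.
#' @param range `c(low, high)` linear range (µg/mL), low < high.
#' @param lod,loq Limits of detection/quantitation (µg/mL); `lod < loq`.
#' @return A `calibration_curve` object.
#' @export
calibration_curve <- function(analyte, slope, intercept, r, range,
                              lod = NA_real_, loq = NA_real_) {
  stopifnot(slope > 0, length(range) == 2L, range[1L] < range[2L],
            r >= -1, r <= 1)
  if (!is.na(lod) && !is.na(loq) && !(lod < loq)) stop("lod must be < loq")
  structure(list(analyte = analyte, slope = slope, intercept = intercept,
                 r = r, range = as.numeric(range), lod = lod, loq = loq),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("%s: y = %.4gx %+.4g (r = %.5g), linear %.3g-%.3g ug/mL, LOD %.3g, LOQ %.3g\n",
              x$analyte, x$slope, x$intercept, x$r, x$range[1L], x$range[2L],
              x$lod, x$loq))
  invisible(x)
}

#' Fit a calibration line
#'
#' Ordinary least squares of peak area on concentration; `r` is the Pearson
#' correlation of the points and the linear range is the span of the fitted
#' concentrations.
#'
#' @param concentration Concentrations (µg/mL), >= 3 points with >= 2
#'   distinct values.
#' @param area Peak areas (mAU·min).
#' @param analyte Label stored on the curve.
#' @return A [calibration_curve] (no LOD/LOQ; see [estimate_lod_loq()]).
#' @export
fit_calibration <- function(concentration, area, analyte = NA_character_) {
  stopifnot(length(concentration) == length(area), length(concentration) >= 3L)
  if (length(unique(concentration)) < 2L)
    stop("all concentrations equal: singular fit")
  fit <- stats::lm(area ~ concentration)
  co <- stats::coef(fit)
  calibration_curve(analyte = analyte, slope = unname(co[2L]),
                    intercept = unname(co[1L]),
                    r = stats::cor(concentration, area),
                    range = range(concentration))
}

#' Invert a calibration line
#'
#' Concentration = (area - intercept) / slope. Values below zero are clamped
#' to 0 with a warning (sub-blank signal); values outside the linear range
#' raise a range-violation error unless extrapolation is allowed, in which
#' case a warning is recorded.
#'
#' @param curve A [calibration_curve].
#' @param area Peak area (mAU·min).
#' @param allow_extrapolation Permit concentrations outside the linear range.
#' @return Concentration (µg/mL).
#' @export
invert_calibration <- function(curve, area, allow_extrapolation = FALSE) {
  stopifnot(inherits(curve, "calibration_curve"), curve$slope != 0)
  x <- (area - curve$intercept) / curve$slope
  if (x < 0) {
    warning("sub-blank signal for ", curve$analyte, ": concentration clamped to 0")
    return(0)
  }
  out <- x < curve$range[1L] - 1e-9 || x > curve$range[2L] + 1e-9
  if (out) {
    msg <- sprintf("concentration %.4g ug/mL outside linear range [%.4g, %.4g] for %s",
                   x, curve$range[1L], curve$range[2L], curve$analyte)
    if (!allow_extrapolation)
      stop(errorCondition(msg, class = c("dilongqc_range_error", "error", "condition")))
    warning(msg)
  }
  x
}

#' Sample preparation constants
#'
#' The extraction recipe linking extract concentration to dry-weight
#' content: `mass` g of powdered material extracted into `volume` mL,
#' optionally diluted.
#'
#' @param mass Sample mass (g), default 1.0.
#' @param volume Extraction volume (mL), default 20.
#' @param dilution_factor Dilution applied before injection, >= 1.
#' @return A `sample_prep` object.
#' @export
sample_prep <- function(mass = 1.0, volume = 20, dilution_factor = 1) {
  stopifnot(mass > 0, volume > 0, all(dilution_factor >= 1))
  structure(list(mass = mass, volume = volume, dilution_factor = dilution_factor),
            class = "sample_prep")
}

#' Convert extract concentration to dry-weight content
#'
#' content (µg/g) = concentration (µg/mL) x volume (mL) x dilution / mass (g).
#'
#' @param conc Measured (injected) concentration, µg/mL.
#' @param prep A [sample_prep].
#' @return Content, µg per g of dried material.
#' @export
concentration_to_content <- function(conc, prep = sample_prep()) {
  stopifnot(inherits(prep, "sample_prep"))
  conc * prep$volume * prep$dilution_factor / prep$mass
}

#' Estimate LOD and LOQ from a dilution series
#'
#' LOD and LOQ are the concentrations at signal-to-noise 3 and 10, found by
#' linear interpolation in (concentration, S/N). Below the lowest measured
#' point the first segment is extrapolated down to concentration 0.
#'
#' @param concentration Increasing concentrations (µg/mL).
#' @param snr Matching S/N values; must increase with concentration. A
#'   series not reaching an interpolation target yields `NA` for that limit
#'   with a warning.
#' @return Named numeric `c(lod, loq)` (µg/mL).
#' @export
estimate_lod_loq <- function(concentration, snr) {
  ord <- order(concentration)
  concentration <- concentration[ord]; snr <- snr[ord]
  stopifnot(length(concentration) >= 2L)
  if (any(diff(snr) <= 0)) stop("S/N series must increase with concentration")
  at <- function(target) {
    if (target > max(snr)) {
      warning("series does not bracket S/N ", target, "; returning NA")
      return(NA_real_)
    }
    if (target >= snr[1L]) return(stats::approx(snr, concentration, xout = target)$y)
    # extrapolate the first segment toward zero
    s <- (concentration[2L] - concentration[1L]) / (snr[2L] - snr[1L])
    max(0, concentration[1L] + s * (target - snr[1L]))
  }
  c(lod = at(3), loq = at(10))
}

#' Quantify one batch from its assigned peak table
#'
#' For each calibrated analyte: a missing peak or S/N < 3 is reported as
#' not detected (`nd`, content `NA`); S/N in [3, 10) is quantified but
#' flagged `below_loq`; otherwise the calibration is inverted and the
#' concentration converted to µg/g through the sample preparation,
#' reapplying any per-analyte dilution factor.
#'
#' @param table An analyte-assigned [peak_table].
#' @param curves Named list of [calibration_curve] objects; every detected,
#'   assigned analyte must have one.
#' @param prep A [sample_prep].
#' @param dilution Optional named per-analyte dilution factors (overriding
#'   `prep$dilution_factor`), e.g. from the study manifest; defaults to the
#'   table's `dilution` attribute when present.
#' @return Data frame: batch_id, analyte, area, snr, concentration_ug_per_ml,
#'   content_ug_per_g, flag (`ok` | `below_loq` | `nd`).
#' @export
quantify_batch <- function(table, curves = reference_calibration_curves(),
                           prep = sample_prep(), dilution = NULL) {
  stopifnot(inherits(table, "peak_table"))
  dilution <- dilution %||% attr(table, "dilution")
  assigned <- table$analyte[!is.na(table$analyte)]
  no_curve <- setdiff(assigned, names(curves))
  if (length(no_curve))
    stop("missing calibration for detected analyte(s): ",
         paste(no_curve, collapse = ", "))
  rows <- lapply(names(curves), function(a) {
    i <- match(a, table$analyte)
    d <- if (!is.null(dilution) && a %in% names(dilution)) dilution[[a]] else prep$dilution_factor
    if (is.na(i) || table$snr[i] < 3)
      return(data.frame(batch_id = batch_id_of(table), analyte = a,
                        area = NA_real_, snr = if (is.na(i)) NA_real_ else table$snr[i],
                        concentration_ug_per_ml = NA_real_,
                        content_ug_per_g = NA_real_, flag = "nd",
                        stringsAsFactors = FALSE))
    conc <- invert_calibration(curves[[a]], table$area[i], allow_extrapolation = TRUE)
    pb <- sample_prep(prep$mass, prep$volume, d)
    data.frame(batch_id = batch_id_of(table), analyte = a,
               area = table$area[i], snr = table$snr[i],
               concentration_ug_per_ml = conc,
               content_ug_per_g = concentration_to_content(conc, pb),
               flag = if (table$snr[i] < 10) "below_loq" else "ok",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write calibration and content tables
#'
#' `write_calibration()` mirrors the published calibration layout (analyte,
#' slope, intercept, r, range, LOD, LOQ); `write_contents()` writes the long
#' batch x analyte content table with flags.
#'
#' @param curves Named list of [calibration_curve] objects.
#' @param contents Row-bound output of [quantify_batch()].
#' @param path Output CSV path.
#' @export
write_calibration <- function(curves, path) {
  d <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(analyte = cv$analyte, slope = cv$slope, intercept = cv$intercept,
               r = cv$r, range_low = cv$range[1L], range_high = cv$range[2L],
               lod = cv$lod, loq = cv$loq, stringsAsFactors = FALSE)
  }))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
write_contents <- function(contents, path) {
  utils::write.csv(contents[c("batch_id", "analyte", "content_ug_per_g", "flag")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
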