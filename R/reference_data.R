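#' The six nucleoside markers, in elution order
#'
#' Hypoxanthine, xanthine, uridine, inosine, guanosine and adenosine, the
#' UV-absorbing purine/pyrimidine markers monitored at 260 nm. Order matches
#' elution on the reference gradient.
#'
#' @return Character vector of length six.
#' @export
nucleoside_analytes <- function() {
  c("hypoxanthine", "xanthine", "uridine", "inosine", "guanosine", "adenosine")
}

#' Reference retention times of the six nucleosides
#'
#' Apex retention times (min) on the reference gradient. Inosine, the
#' fingerprint reference peak, elutes at 9.35 min; the remaining analytes are
#' placed inside the 0--15 min gradient window in elution order.
#'
#' @return Named numeric vector (min), names as [nucleoside_analytes()].
#' @export
analyte_retention_times <- function() {
  c(hypoxanthine = 3.20, xanthine = 4.60, uridine = 6.10,
    inosine = 9.35, guanosine = 11.20, adenosine = 13.40)
}

ref_csv <- function(file) {
  path <- system.file("extdata", file, package = "dilongqc", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published calibration table for the six nucleosides
#'
#' Regression line (peak area in mAU·min versus concentration in µg/mL),
#' correlation coefficient, linear range, LOD and LOQ for each analyte, as
#' established on the reference instrument.
#'
#' @return Data frame with columns `analyte`, `slope`, `intercept`, `r`,
#'   `range_low`, `range_high`, `lod`, `loq`.
#' @seealso [reference_calibration_curves()] for the same table as a list of
#'   [calibration_curve] objects.
#' @export
reference_calibration <- function() ref_csv("reference_calibration.csv")

#' @rdname reference_calibration
#' @export
reference_calibration_curves <- function() {
  tab <- reference_calibration()
  curves <- lapply(seq_len(nrow(tab)), function(i) {
    calibration_curve(
      analyte = tab$analyte[i], slope = tab$slope[i], intercept = tab$intercept[i],
      r = tab$r[i], range = c(tab$range_low[i], tab$range_high[i]),
      lod = tab$lod[i], loq = tab$loq[i]
    )
  })
  stats::setNames(curves, tab$analyte)
}

#' Published nucleoside contents of the 42 reference batches
#'
#' Per-batch contents (µg per g of dried material, duplicate determination)
#' of the six nucleosides in 22 authenticated *P. aspergillum* batches and 20
#' adulterant batches (*A. obscuritoporus*, *M. magna*). `NA` means not
#' detected; adenosine is absent from every authentic batch.
#'
#' @return Data frame with columns `batch_id`, `species` and one column per
#'   analyte.
#' @export
reference_contents <- function() ref_csv("reference_contents.csv")

#' Species composition profiles derived from the reference batches
#'
#' Per-species content ranges (min--max over the reference batches, µg/g) for
#' each nucleoside, used by the study generator to sample batch compositions.
#' Adenosine is flagged absent (range exactly (0, 0)) for
#' *Pheretima aspergillum* and present for both adulterant species.
#'
#' @return Named list of `species_profile` objects, each with fields
#'   `species_name`, `analyte_content_ranges` (2-row matrix, rows low/high)
#'   and `adenosine_present`.
#' @export
species_profiles <- function() {
  contents <- reference_contents()
  analytes <- nucleoside_analytes()
  profs <- lapply(split(contents, contents$species), function(d) {
    rng <- sapply(analytes, function(a) {
      v <- d[[a]]
      if (all(is.na(v))) c(0, 0) else range(v, na.rm = TRUE)
    })
    rownames(rng) <- c("low", "high")
    species_profile(d$species[1L], rng, adenosine_present = any(!is.na(d$adenosine)))
  })
  profs[unique(contents$species)]
}

#' Construct a species composition profile
#'
#' @param species_name Species label.
#' @param analyte_content_ranges 2 x n matrix (rows `low`, `high`, µg/g),
#'   columns named by analyte.
#' @param adenosine_present Logical; must agree with the adenosine range
#'   being (0, 0).
#' @return A `species_profile` object.
#' @export
species_profile <- function(species_name, analyte_content_ranges, adenosine_present) {
  rng <- analyte_content_ranges
  stopifnot(is_string(species_name), is.matrix(rng), nrow(rng) == 2L,
            all(is.finite(rng)), all(rng >= 0), all(rng[1L, ] <= rng[2L, ]))
  if ("adenosine" %in% colnames(rng)) {
    ade_zero <- all(rng[, "adenosine"] == 0)
    if (ade_zero == isTRUE(adenosine_present))
      stop("adenosine_present must be FALSE exactly when the adenosine range is (0, 0)")
  }
  structure(list(species_name = species_name,
                 analyte_content_ranges = rng,
                 adenosine_present = isTRUE(adenosine_present)),
            class = "species_profile")
}

#' Default 42-batch study design
#'
#' The reference study roster: batches 1--22 authenticated
#' *P. aspergillum*, 23--31 *A. obscuritoporus*, 32--42 *M. magna*
#' (22 authentic, 20 adulterant batches).
#'
#' @param seed Integer seed stored with the design.
#' @return A `study_design` object: data frame of (`batch_id`, `species`,
#'   `role`) plus `seed`, `n_authentic`, `n_adulterant`.
#' @export
default_study_design <- function(seed = 42L) {
  contents <- reference_contents()
  study_design(batch_id = contents$batch_id, species = contents$species, seed = seed)
}

#' @rdname default_study_design
#' @param batch_id Unique batch identifiers.
#' @param species Species label per batch.
#' @export
study_design <- function(batch_id, species, seed = 42L) {
  stopifnot(length(batch_id) == length(species), !anyDuplicated(batch_id))
  role <- ifelse(species == "Pheretima aspergillum", "authentic", "adulterant")
  structure(list(
    batches = data.frame(batch_id = batch_id, species = species, role = role,
                         stringsAsFactors = FALSE),
    n_authentic = sum(role == "authentic"),
    n_adulterant = sum(role == "adulterant"),
    seed = as.integer(seed)
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: %d batches (%d authentic, %d adulterant), seed %d\n",
              nrow(x$batches), x$n_authentic, x$n_adulterant, x$seed))
  invisible(x)
}
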