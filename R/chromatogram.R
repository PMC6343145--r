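#' Construct a single-wavelength chromatogram
#'
#' A chromatogram is a uniformly sampled time/intensity trace from a
#' single monitored detector wavelength.
#'
#' @param time Strictly increasing, uniformly spaced time grid (min).
#' @param intensity Detector signal (mAU), same length as `time`.
#' @param batch_id Optional batch label.
#' @param wavelength Detection wavelength (nm), 260 by default.
#' @return A `chromatogram` object.
#' @export
chromatogram <- function(time, intensity, batch_id = NA_character_, wavelength = 260) {
  stopifnot(is.numeric(time), is.numeric(intensity),
            length(time) == length(intensity), length(time) >= 2L)
  if (!all(is.finite(time)) || !all(is.finite(intensity)))
    stop("chromatogram time and intensity must be finite")
  steps <- diff(time)
  if (any(steps <= 0)) stop("time grid must be strictly increasing")
  if (diff(range(steps)) > 1e-9) stop("time grid must be uniform (tolerance 1e-9)")
  structure(list(time = as.numeric(time), intensity = as.numeric(intensity),
                 batch_id = as.character(batch_id), wavelength = wavelength),
            class = "chromatogram")
}

grid_step <- function(chrom) chrom$time[2L] - chrom$time[1L]

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("Chromatogram %s: %d points, %.2f-%.2f min, %g nm, max %.2f mAU\n",
              x$batch_id, length(x$time), min(x$time), max(x$time),
              x$wavelength, max(x$intensity)))
  invisible(x)
}

#' @export
as.data.frame.chromatogram <- function(x, ...) {
  data.frame(time_min = x$time, intensity_mau = x$intensity)
}

#' Read and write chromatogram CSV traces
#'
#' The on-disk format is a two-column CSV with header
#' `time_min,intensity_mau`, one row per grid point.
#'
#' @param path File path.
#' @param batch_id Batch label to attach on read (defaults to the file name).
#' @param wavelength Detection wavelength (nm).
#' @return `read_chromatogram()` returns a [chromatogram];
#'   `write_chromatogram()` returns `path` invisibly.
#' @export
read_chromatogram <- function(path, batch_id = NULL, wavelength = 260) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_min", "intensity_mau") %in% names(d)))
    stop("malformed chromatogram CSV (need columns time_min, intensity_mau): ", path)
  chromatogram(d$time_min, d$intensity_mau,
               batch_id = batch_id %||% sub("\\.csv$", "", basename(path)),
               wavelength = wavelength)
}

#' @rdname read_chromatogram
#' @param chrom A [chromatogram].
#' @export
write_chromatogram <- function(chrom, path) {
  utils::write.csv(as.data.frame(chrom), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
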