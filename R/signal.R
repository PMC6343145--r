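#' Peak table
#'
#' Detected chromatographic peaks for one batch: apex retention time (min),
#' baseline-corrected height (mAU), trapezoid area between integration
#' bounds (mAU·min), bounds (min), signal-to-noise ratio, and an optional
#' analyte label. Rows are ordered by apex retention time.
#'
#' @param peaks Data frame with columns `analyte`, `apex_rt`, `height`,
#'   `area`, `left_bound`, `right_bound`, `snr` (may be empty/NULL).
#' @param batch_id Batch label carried as an attribute.
#' @return A `peak_table` (data frame subclass).
#' @export
peak_table <- function(peaks = NULL, batch_id = NA_character_) {
  cols <- c("analyte", "apex_rt", "height", "area", "left_bound", "right_bound", "snr")
  if (is.null(peaks) || nrow(peaks) == 0L) {
    peaks <- data.frame(analyte = character(), apex_rt = numeric(),
                        height = numeric(), area = numeric(),
                        left_bound = numeric(), right_bound = numeric(),
                        snr = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(cols %in% names(peaks)))
  peaks <- peaks[order(peaks$apex_rt), cols, drop = FALSE]
  if (nrow(peaks)) {
    stopifnot(all(peaks$left_bound < peaks$apex_rt),
              all(peaks$apex_rt < peaks$right_bound),
              all(peaks$area > 0), all(peaks$height > 0),
              !any(duplicated(peaks$apex_rt)))
  }
  rownames(peaks) <- NULL
  structure(peaks, class = c("peak_table", "data.frame"), batch_id = as.character(batch_id))
}

batch_id_of <- function(x) attr(x, "batch_id") %||% NA_character_

# robust white-noise floor from first differences; zero for smooth traces
noise_floor <- function(y) stats::mad(diff(y)) / sqrt(2)

#' Baseline correction by morphological opening
#'
#' Estimates the baseline as a lightly smoothed morphological opening
#' (rolling minimum followed by rolling maximum) of the pre-smoothed trace,
#' and subtracts it. The opening reproduces constant offsets and linear
#' ramps exactly while removing any peak narrower than `window`, so the
#' operation is idempotent up to the noise level.
#'
#' @param chrom A [chromatogram].
#' @param window Structuring-element width (min); must exceed the grid step,
#'   be wider than the peaks, and not exceed the trace span.
#' @param smooth Pre-smoothing window (min) applied before the opening to
#'   keep the noise floor from biasing the rolling minimum.
#' @return A baseline-corrected [chromatogram].
#' @export
correct_baseline <- function(chrom, window = 1.0, smooth = 0.2) {
  stopifnot(inherits(chrom, "chromatogram"))
  step <- grid_step(chrom)
  if (window <= step) stop("window must exceed the grid step")
  if (window > diff(range(chrom$time))) stop("window exceeds the trace span")
  k_open <- as.integer(round(window / step))
  k_sm <- max(3L, as.integer(round(smooth / step)))
  y <- chrom$intensity
  ys <- movavg(y, k_sm)
  baseline <- movavg(roll_extreme(roll_extreme(ys, k_open, pmin), k_open, pmax), k_sm)
  chromatogram(chrom$time, y - baseline, batch_id = chrom$batch_id,
               wavelength = chrom$wavelength)
}

#' Detect peaks on a baseline-corrected chromatogram
#'
#' Finds local maxima on a lightly smoothed copy of the trace, keeps those
#' whose baseline-corrected height passes both the absolute and the
#' signal-to-noise thresholds, and prunes noise apexes by requiring a
#' prominence (apex above the deeper flanking valley, measured on the
#' smoothed trace) of at least half the apex height. Integration bounds are
#' placed at flanking valleys or where the signal falls below a small
#' fraction of the apex height; areas are trapezoid integrals of the
#' unsmoothed trace between the bounds.
#'
#' @param chrom A baseline-corrected [chromatogram].
#' @param min_snr Minimum height / noise-floor ratio (default 10, the
#'   quantifiable-peak convention; use 3 for detectable peaks).
#' @param min_height Minimum baseline-corrected apex height (mAU); default
#'   3 x the estimated noise floor.
#' @param bound_frac Height fraction at which a bound is placed when no
#'   valley intervenes (default 1e-6, i.e. effectively baseline-to-baseline
#'   on noiseless traces).
#' @return A [peak_table] (empty for flat or pure-noise input).
#' @export
detect_peaks <- function(chrom, min_snr = 10, min_height = NULL, bound_frac = 1e-6) {
  stopifnot(inherits(chrom, "chromatogram"))
  y <- chrom$intensity
  tg <- chrom$time
  n <- length(y)
  noise <- noise_floor(y)
  if (noise < 1e-12) noise <- 0
  if (is.null(min_height)) min_height <- max(3 * noise, 1e-9)
  ys <- movavg(y, 9L)
  d <- diff(ys)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  cand <- cand[y[cand] >= min_height]
  if (noise > 0) cand <- cand[y[cand] / noise >= min_snr]
  # prominence pruning on the smoothed trace: drop the weakest apex whose
  # rise above the deeper neighbouring valley is < half its height, repeat
  while (length(cand)) {
    prom <- prominences(ys, cand)
    bad <- which(prom < pmax(min_height, 0.5 * ys[cand]))
    if (!length(bad)) break
    cand <- cand[-bad[which.min(prom[bad])]]
  }
  if (!length(cand)) return(peak_table(batch_id = chrom$batch_id))
  cap <- as.integer(round(1.0 / (tg[2L] - tg[1L])))  # max half-width 1 min
  rows <- lapply(cand, function(i) {
    apex <- (max(1L, i - 4L):min(n, i + 4L))[which.max(y[max(1L, i - 4L):min(n, i + 4L)])]
    h <- y[apex]
    thr <- max(bound_frac * h, 1e-12)
    rise_tol <- max(3 * noise, 1e-9)
    # walk outward tracking the running minimum; stop at the baseline
    # threshold or when the smoothed trace climbs clear of the minimum
    # (the valley before an adjacent peak); bound sits at the minimum
    walk <- function(dir) {
      j <- apex
      run_min <- ys[apex]; min_i <- apex
      while (abs(j - apex) < cap) {
        j <- j + dir
        if (j < 1L || j > n) return(min_i)
        if (ys[j] < run_min) { run_min <- ys[j]; min_i <- j }
        if (ys[j] <= thr) return(j)
        if (ys[j] > run_min + rise_tol) return(min_i)
      }
      min_i
    }
    lb <- min(walk(-1L), max(1L, apex - 1L))
    rb <- max(walk(1L), min(n, apex + 1L))
    if (lb >= apex || rb <= apex) return(NULL)
    data.frame(analyte = NA_character_, apex_rt = tg[apex], height = h,
               area = trapz(tg[lb:rb], y[lb:rb]),
               left_bound = tg[lb], right_bound = tg[rb],
               snr = if (noise > 0) h / noise else Inf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$area > 0 & out$height > 0, , drop = FALSE]
  out <- out[!duplicated(out$apex_rt), , drop = FALSE]
  peak_table(out, batch_id = chrom$batch_id)
}

# prominence of each apex index: height above the higher of the two valley
# minima separating it from its neighbouring (or trace-end) apexes
prominences <- function(ys, cand) {
  n <- length(ys)
  k <- length(cand)
  vapply(seq_len(k), function(j) {
    left_lim <- if (j > 1L) cand[j - 1L] else 1L
    right_lim <- if (j < k) cand[j + 1L] else n
    vl <- min(ys[left_lim:cand[j]])
    vr <- min(ys[cand[j]:right_lim])
    ys[cand[j]] - max(vl, vr)
  }, numeric(1L))
}

#' Signal-to-noise ratio of a peak against a quiet window
#'
#' S/N is defined as the baseline-corrected peak height divided by the
#' standard deviation (n - 1 denominator) of the trace within a peak-free
#' quiet window. A noiseless window yields `Inf`.
#'
#' @param chrom A baseline-corrected [chromatogram].
#' @param peak One-row slice of a [peak_table] (or a list with `height`,
#'   `left_bound`, `right_bound`).
#' @param quiet_window `c(start, end)` in min; must not overlap the peak.
#' @return Dimensionless S/N.
#' @export
estimate_snr <- function(chrom, peak, quiet_window) {
  stopifnot(inherits(chrom, "chromatogram"), length(quiet_window) == 2L,
            quiet_window[1L] < quiet_window[2L])
  if (quiet_window[1L] < peak$right_bound && quiet_window[2L] > peak$left_bound)
    stop("quiet_window overlaps the peak")
  sel <- chrom$time >= quiet_window[1L] & chrom$time <= quiet_window[2L]
  if (sum(sel) < 2L) stop("quiet_window contains fewer than 2 points")
  s <- stats::sd(chrom$intensity[sel])
  if (s == 0) Inf else peak$height / s
}

#' Assign analyte labels to detected peaks by retention time
#'
#' Each analyte claims the nearest peak within `rt_tolerance` of its
#' reference retention time; peaks claimed by no analyte stay unlabelled.
#' An analyte claims at most one peak.
#'
#' @param table A [peak_table].
#' @param analyte_rts Named reference retention times (min).
#' @param rt_tolerance Matching half-window (min), > 0; reference times
#'   closer together than twice the tolerance are rejected as ambiguous.
#' @return The [peak_table] with the `analyte` column filled in.
#' @export
assign_analytes <- function(table, analyte_rts = analyte_retention_times(),
                            rt_tolerance = 0.10) {
  stopifnot(inherits(table, "peak_table"), rt_tolerance > 0)
  rts <- sort(analyte_rts)
  if (length(rts) > 1L && any(diff(rts) < 2 * rt_tolerance))
    stop("analyte retention times closer than 2 x rt_tolerance: ambiguous assignment")
  if (!nrow(table)) return(table)
  table$analyte <- NA_character_
  for (a in names(analyte_rts)) {
    dist <- abs(table$apex_rt - analyte_rts[[a]])
    ok <- which(dist <= rt_tolerance & is.na(table$analyte))
    if (length(ok)) table$analyte[ok[which.min(dist[ok])]] <- a
  }
  peak_table(table, batch_id = batch_id_of(table))
}

#' Write a peak table CSV
#'
#' Columns: batch_id, analyte, apex_rt_min, height_mau, area_mau_min,
#' left_min, right_min, snr.
#'
#' @param table A [peak_table] (or several row-bound ones with a `batch_id`
#'   column already present).
#' @param path Output path.
#' @export
write_peak_table <- function(table, path) {
  d <- as.data.frame(table)
  if (!"batch_id" %in% names(d)) d <- cbind(batch_id = batch_id_of(table), d)
  names(d) <- sub("^apex_rt$", "apex_rt_min", names(d))
  names(d) <- sub("^height$", "height_mau", names(d))
  names(d) <- sub("^area$", "area_mau_min", names(d))
  names(d) <- sub("^left_bound$", "left_min", names(d))
  names(d) <- sub("^right_bound$", "right_min", names(d))
  d <- d[c("batch_id", "analyte", "apex_rt_min", "height_mau", "area_mau_min",
           "left_min", "right_min", "snr")]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
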