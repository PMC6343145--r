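#' Match common peaks across batches
#'
#' Pools apex retention times from all peak tables and clusters them along
#' the time axis by single linkage: a new cluster starts wherever the gap to
#' the previous apex exceeds `rt_tolerance`, and any cluster whose diameter
#' exceeds twice the tolerance is split at its largest internal gap (ties
#' resolved toward the earlier-eluting side). One cluster is one common
#' peak; a batch's area for a common peak is 0 when the batch lacks it, and
#' prevalence is the fraction of batches containing it.
#'
#' @param tables List of >= 2 [peak_table] objects (distinct batch ids).
#' @param rt_tolerance Single-linkage gap (min).
#' @return A `common_peak_table`: list with `peaks` (index, mean_rt,
#'   prevalence), `areas` and `rts` (batch x common-peak matrices; 0 / NA
#'   where absent), `batch_ids`, and empty `rrt`/`rpa` slots filled by
#'   [relative_metrics()].
#' @export
match_common_peaks <- function(tables, rt_tolerance = 0.10) {
  if (!length(tables)) stop("empty table list")
  if (length(tables) < 2L) stop("need at least 2 peak tables")
  batch_ids <- vapply(tables, batch_id_of, character(1L))
  if (anyDuplicated(batch_ids)) stop("duplicate batch ids in tables")
  pooled <- do.call(rbind, lapply(seq_along(tables), function(i) {
    d <- as.data.frame(tables[[i]])
    if (!nrow(d)) return(NULL)
    cbind(batch = i, d[c("apex_rt", "area")])
  }))
  if (is.null(pooled) || !nrow(pooled)) stop("no peaks in any table")
  ord <- order(pooled$apex_rt)
  pooled <- pooled[ord, , drop = FALSE]
  cl <- cumsum(c(1L, as.integer(diff(pooled$apex_rt) > rt_tolerance)))
  cl <- split_wide_clusters(pooled$apex_rt, cl, 2 * rt_tolerance)
  groups <- split(seq_len(nrow(pooled)), cl)
  nb <- length(tables)
  np <- length(groups)
  areas <- matrix(0, nb, np, dimnames = list(batch_ids, NULL))
  rts <- matrix(NA_real_, nb, np, dimnames = list(batch_ids, NULL))
  mean_rt <- numeric(np)
  prevalence <- numeric(np)
  for (p in seq_len(np)) {
    g <- pooled[groups[[p]], , drop = FALSE]
    mean_rt[p] <- mean(g$apex_rt)
    prevalence[p] <- length(unique(g$batch)) / nb
    for (b in unique(g$batch)) {
      gb <- g[g$batch == b, , drop = FALSE]
      best <- which.max(gb$area)  # keep the dominant peak if a batch has two
      areas[b, p] <- gb$area[best]
      rts[b, p] <- gb$apex_rt[best]
    }
  }
  structure(list(
    peaks = data.frame(index = seq_len(np), mean_rt = mean_rt, prevalence = prevalence),
    areas = areas, rts = rts, batch_ids = batch_ids, rrt = NULL, rpa = NULL
  ), class = "common_peak_table")
}

# recursively split clusters whose RT diameter exceeds max_diam at the
# largest internal gap (earliest such gap on ties)
split_wide_clusters <- function(rt, cl, max_diam) {
  repeat {
    changed <- FALSE
    for (id in unique(cl)) {
      idx <- which(cl == id)
      if (length(idx) < 2L) next
      if (diff(range(rt[idx])) > max_diam) {
        gaps <- diff(rt[idx])
        cut <- which.max(gaps)  # which.max takes the first (earlier) maximum
        cl[idx[(cut + 1L):length(idx)]] <- max(cl) + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  as.integer(factor(cl, levels = unique(cl[order(rt)])))
}

#' @export
print.common_peak_table <- function(x, ...) {
  cat(sprintf("Common peak table: %d batches x %d common peaks\n",
              length(x$batch_ids), nrow(x$peaks)))
  print(x$peaks)
  invisible(x)
}

#' Select the fingerprint reference peak
#'
#' Default strategy `"max-mean-area-ubiquitous"`: among common peaks present
#' in every batch (prevalence 1), the one with the highest mean area. A
#' fixed-time strategy `"fixed-rt:<minutes>"` selects the common peak whose
#' mean retention time is nearest the given time.
#'
#' @param cpt A `common_peak_table`.
#' @param strategy Strategy string as above.
#' @return Common-peak index (integer).
#' @export
select_reference_peak <- function(cpt, strategy = "max-mean-area-ubiquitous") {
  stopifnot(inherits(cpt, "common_peak_table"), is_string(strategy))
  if (grepl("^fixed-rt:", strategy)) {
    t0 <- as.numeric(sub("^fixed-rt:", "", strategy))
    if (!is.finite(t0)) stop("malformed fixed-rt strategy: ", strategy)
    return(cpt$peaks$index[which.min(abs(cpt$peaks$mean_rt - t0))])
  }
  if (strategy != "max-mean-area-ubiquitous") stop("unknown strategy: ", strategy)
  ubiq <- which(cpt$peaks$prevalence >= 1 - 1e-12)
  if (!length(ubiq)) stop("no common peak present in every batch; no valid reference")
  ubiq[which.max(colMeans(cpt$areas)[ubiq])]
}

#' Relative retention times and relative peak areas
#'
#' Fills the `rrt` and `rpa` slots of a common peak table: per batch, each
#' common peak's retention time and area divided by the reference peak's.
#' The reference column is identically 1.
#'
#' @param cpt A `common_peak_table`.
#' @param ref_index Reference common-peak index (see
#'   [select_reference_peak()]).
#' @return The `common_peak_table` with `rrt`, `rpa` and `reference_index`
#'   filled in.
#' @export
relative_metrics <- function(cpt, ref_index) {
  stopifnot(inherits(cpt, "common_peak_table"),
            ref_index %in% cpt$peaks$index)
  ref_area <- cpt$areas[, ref_index]
  zero <- ref_area <= 0
  if (any(zero))
    stop("zero reference area in batch(es): ",
         paste(cpt$batch_ids[zero], collapse = ", "))
  cpt$rrt <- cpt$rts / cpt$rts[, ref_index]
  cpt$rpa <- cpt$areas / ref_area
  cpt$reference_index <- as.integer(ref_index)
  cpt
}

#' Mean fusion chromatogram
#'
#' Pointwise arithmetic mean of a set of (baseline-corrected) chromatograms
#' sharing one grid: the simulative mean chromatogram that represents the
#' material's consensus fingerprint.
#'
#' @param chroms List of [chromatogram] objects on a common grid.
#' @return A [chromatogram] with batch id `"mean_fusion"`.
#' @export
mean_fusion <- function(chroms) {
  if (!length(chroms)) stop("empty chromatogram list")
  t0 <- chroms[[1L]]$time
  same <- vapply(chroms, function(ch)
    length(ch$time) == length(t0) && max(abs(ch$time - t0)) <= 1e-9, logical(1L))
  if (!all(same)) stop("chromatograms are on mismatched grids; resample first")
  m <- rowMeans(vapply(chroms, `[[`, numeric(length(t0)), "intensity"))
  chromatogram(t0, m, batch_id = "mean_fusion",
               wavelength = chroms[[1L]]$wavelength)
}

#' Similarity index against the mean fusion chromatogram
#'
#' Pearson correlation (default) or cosine similarity between a batch trace
#' and the mean fusion vector, computed on the full shared grid.
#'
#' @param chrom A [chromatogram] (baseline-corrected).
#' @param mean_vector A [chromatogram] or numeric vector of matching length.
#' @param method `"correlation"` (Pearson) or `"cosine"`.
#' @return Similarity in `[-1, 1]`.
#' @export
similarity <- function(chrom, mean_vector, method = c("correlation", "cosine")) {
  method <- match.arg(method)
  x <- if (inherits(chrom, "chromatogram")) chrom$intensity else as.numeric(chrom)
  y <- if (inherits(mean_vector, "chromatogram")) mean_vector$intensity else as.numeric(mean_vector)
  if (length(x) != length(y)) stop("trace and mean vector lengths differ")
  if (method == "correlation") {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero-variance trace: similarity undefined")
    stats::cor(x, y)
  } else {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) stop("zero-norm trace: similarity undefined")
    sum(x * y) / (nx * ny)
  }
}

#' Peak-vector similarity
#'
#' Alternative similarity mode: Pearson correlation between one batch's
#' relative-peak-area vector and the mean relative-peak-area vector over all
#' batches. Requires [relative_metrics()] to have been applied.
#'
#' @param cpt A `common_peak_table` with `rpa` filled in.
#' @param batch_id Batch to score.
#' @return Similarity in `[-1, 1]`.
#' @export
rpa_similarity <- function(cpt, batch_id) {
  if (is.null(cpt$rpa)) stop("run relative_metrics() first")
  b <- match(as.character(batch_id), cpt$batch_ids)
  if (is.na(b)) stop("unknown batch: ", batch_id)
  similarity(cpt$rpa[b, ], colMeans(cpt$rpa))
}

#' Characteristic peaks of a fingerprint
#'
#' Common peaks whose prevalence across batches meets the threshold.
#'
#' @param cpt A `common_peak_table`.
#' @param prevalence_threshold Fraction in (0, 1]; default 0.9.
#' @return Integer vector of common-peak indices.
#' @export
characteristic_peaks <- function(cpt, prevalence_threshold = 0.9) {
  stopifnot(inherits(cpt, "common_peak_table"),
            prevalence_threshold > 0, prevalence_threshold <= 1)
  cpt$peaks$index[cpt$peaks$prevalence >= prevalence_threshold - 1e-12]
}

#' Build a fingerprint model from baseline-corrected chromatograms
#'
#' Convenience composition: detect-free model construction from already
#' detected peak tables and their traces — common-peak matching, reference
#' selection, relative metrics, mean fusion and characteristic peaks.
#'
#' @param chroms List of baseline-corrected [chromatogram] objects.
#' @param tables Matching list of [peak_table] objects.
#' @param rt_tolerance Common-peak matching tolerance (min).
#' @param prevalence_threshold Characteristic-peak threshold.
#' @param strategy Reference-peak strategy (see [select_reference_peak()]).
#' @param species_label Label stored with the model.
#' @return A `fingerprint_model`: list with `common_peaks`
#'   (`common_peak_table`), `reference_peak_index`, `mean_vector`
#'   ([chromatogram]), `characteristic_peaks`, `species_label`.
#' @export
build_fingerprint <- function(chroms, tables, rt_tolerance = 0.10,
                              prevalence_threshold = 0.9,
                              strategy = "max-mean-area-ubiquitous",
                              species_label = NA_character_) {
  cpt <- match_common_peaks(tables, rt_tolerance)
  ref <- select_reference_peak(cpt, strategy)
  cpt <- relative_metrics(cpt, ref)
  structure(list(common_peaks = cpt,
                 reference_peak_index = ref,
                 mean_vector = mean_fusion(chroms),
                 characteristic_peaks = characteristic_peaks(cpt, prevalence_threshold),
                 species_label = species_label),
            class = "fingerprint_model")
}

#' @export
print.fingerprint_model <- function(x, ...) {
  cat(sprintf("Fingerprint model (%s): %d common peaks, %d characteristic, reference peak %d at %.2f min\n",
              x$species_label, nrow(x$common_peaks$peaks),
              length(x$characteristic_peaks), x$reference_peak_index,
              x$common_peaks$peaks$mean_rt[x$reference_peak_index]))
  invisible(x)
}

#' Serialize a fingerprint model
#'
#' Writes `<stem>.json` (reference index, characteristic peaks, common-peak
#' summary, pointer to the mean-vector CSV) and `<stem>_mean.csv` (the mean
#' fusion chromatogram).
#'
#' @param model A `fingerprint_model`.
#' @param stem Output path stem (no extension).
#' @export
write_fingerprint <- function(model, stem) {
  mean_path <- paste0(stem, "_mean.csv")
  write_chromatogram(model$mean_vector, mean_path)
  jsonlite::write_json(list(
    species_label = model$species_label,
    reference_peak_index = model$reference_peak_index,
    characteristic_peaks = model$characteristic_peaks,
    common_peaks = model$common_peaks$peaks,
    mean_vector_file = basename(mean_path)
  ), paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
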