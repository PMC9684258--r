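#' Global field power
#'
#' The global field power (GFP) at a time instant is the standard deviation
#' of the potential across all electrodes at that instant, computed with
#' divisor N (population SD). On average-referenced data the per-sample mean
#' is zero, so GFP equals the root-mean-square potential and is invariant to
#' the original recording reference.
#'
#' @param rec An [eeg_recording] (average-referenced) or a channels x samples
#'   matrix.
#' @return An object of class `gfp_series`: list with `values` (microvolts,
#'   one per sample) and `fs`.
#' @export
global_field_power <- function(rec) {
  if (inherits(rec, "eeg_recording")) {
    x <- rec$data
    fs <- rec$fs
  } else {
    x <- as.matrix(rec)
    fs <- NA_real_
  }
  if (nrow(x) < 2L) stop("GFP needs at least 2 channels")
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2
  structure(list(values = sqrt(pmax(v, 0)), fs = fs), class = "gfp_series")
}

#' @export
print.gfp_series <- function(x, ...) {
  cat(sprintf("<gfp_series> %d samples @ %g Hz, mean %.3g uV\n",
              length(x$values), x$fs, mean(x$values)))
  invisible(x)
}

#' Locate GFP peaks
#'
#' Finds strict local maxima of the (optionally moving-average smoothed)
#' GFP series; on a plateau the first plateau sample is taken. Peaks closer
#' together than `min_separation_ms` are thinned greedily, keeping the larger
#' peak. Series endpoints are never peaks.
#'
#' Peak detection parameters are conventions, not estimated quantities: the
#' defaults (10 ms separation, no smoothing) suit eyes-closed alpha-dominant
#' resting EEG, where GFP peaks arrive roughly every 50 ms.
#'
#' @param gfp A `gfp_series` from [global_field_power] (or numeric vector, in
#'   which case `fs` must be given).
#' @param min_separation_ms Minimum distance between retained peaks (ms).
#' @param smoothing_ms Width of a centered moving-average window (ms);
#'   0 disables smoothing.
#' @param fs Sampling rate override when `gfp` is a bare vector.
#' @return Integer vector of peak sample indices (possibly empty), strictly
#'   increasing.
#' @export
find_gfp_peaks <- function(gfp, min_separation_ms = 10, smoothing_ms = 0,
                           fs = NULL) {
  if (inherits(gfp, "gfp_series")) {
    v <- gfp$values
    fs <- fs %||% gfp$fs
  } else {
    v <- as.numeric(gfp)
  }
  if (is.null(fs) || is.na(fs)) stop("sampling rate unknown; supply 'fs'")
  n <- length(v)
  if (n < 3L) stop("series too short for peak detection (need >= 3 samples)")
  if (smoothing_ms > 0) {
    w <- max(1L, round(smoothing_ms / 1000 * fs))
    if (w %% 2L == 0L) w <- w + 1L
    v <- stats::filter(v, rep(1 / w, w), sides = 2L)
    v[is.na(v)] <- gfp$values[is.na(v)]
    v <- as.numeric(v)
  }
  interior <- 2:(n - 1L)
  # strict rise; fall may follow a plateau (first plateau sample is the peak)
  rises <- v[interior] > v[interior - 1L]
  cand <- interior[rises]
  is_peak <- vapply(cand, function(i) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    j < n && v[j + 1L] < v[i]
  }, logical(1L))
  peaks <- cand[is_peak]
  if (length(peaks) > 1L && min_separation_ms > 0) {
    min_gap <- min_separation_ms / 1000 * fs
    keep <- order(v[peaks], decreasing = TRUE)  # larger peaks claim first
    taken <- integer(0)
    for (p in peaks[keep]) {
      if (all(abs(p - taken) >= min_gap)) taken <- c(taken, p)
    }
    peaks <- sort(taken)
  }
  as.integer(peaks)
}

#' Extract scalp maps at GFP peaks
#'
#' Copies the average-referenced field at each peak instant. The resulting
#' peaks x channels matrix is the input to microstate clustering and
#' backfitting.
#'
#' @param rec An [eeg_recording].
#' @param peaks Integer sample indices from [find_gfp_peaks].
#' @return An object of class `peak_maps`: list with `maps` (peaks x
#'   channels), `peaks` (indices), `fs`, `n_samples`, `montage` and `id`.
#' @export
extract_peak_maps <- function(rec, peaks) {
  stopifnot(inherits(rec, "eeg_recording"))
  peaks <- as.integer(peaks)
  if (length(peaks) > 0L &&
      (min(peaks) < 1L || max(peaks) > ncol(rec$data))) {
    stop("peak index out of range 1..", ncol(rec$data))
  }
  if (is.unsorted(peaks, strictly = TRUE)) stop("peak indices must be strictly increasing")
  maps <- t(rec$data[, peaks, drop = FALSE])
  if (nrow(maps) > 0L) maps <- maps - rowMeans(maps)  # re-reference each map
  colnames(maps) <- rec$montage$names
  structure(list(maps = maps, peaks = peaks, fs = rec$fs,
                 n_samples = ncol(rec$data), montage = rec$montage,
                 id = rec$subject_id),
            class = "peak_maps")
}

#' @export
print.peak_maps <- function(x, ...) {
  cat(sprintf("<peak_maps> %d peaks x %d channels (recording %s)\n",
              nrow(x$maps), ncol(x$maps), x$id))
  invisible(x)
}
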