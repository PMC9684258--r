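#' EEG recording container
#'
#' Wraps a channels-by-samples matrix of scalp potentials (microvolts) with
#' its sampling rate, montage and study labels. Rows are always in montage
#' order; construction enforces finite samples.
#'
#' @param data Numeric channels x samples matrix (microvolts). Row names, if
#'   present, must match the montage labels.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param montage An [eeg_montage]; defaults to the 19-channel 10/20 set.
#' @param subject_id Subject identifier.
#' @param condition Condition label, conventionally `"pre"` or `"post"`.
#' @param side Epileptic-focus side, `"r-TLE"`, `"l-TLE"` or `NA`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, montage = standard_montage(),
                          subject_id = NA_character_,
                          condition = NA_character_,
                          side = NA_character_) {
  data <- as.matrix(data)
  if (nrow(data) != length(montage$names)) {
    stop("data has ", nrow(data), " rows but montage has ",
         length(montage$names), " electrodes")
  }
  if (!is.null(rownames(data))) {
    if (!identical(rownames(data), montage$names)) {
      missing <- setdiff(montage$names, rownames(data))
      if (length(missing) > 0L) {
        stop("channel(s) missing from data: ", paste(missing, collapse = ", "))
      }
      data <- data[montage$names, , drop = FALSE]
    }
  } else {
    rownames(data) <- montage$names
  }
  if (any(!is.finite(data))) {
    bad <- which(colSums(!is.finite(data)) > 0L)
    stop("non-finite samples at column index(es): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a positive scalar (Hz)")
  }
  structure(list(data = data, fs = as.numeric(fs), montage = montage,
                 subject_id = as.character(subject_id),
                 condition = as.character(condition),
                 side = as.character(side)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  subject: %s  condition: %s  side: %s\n",
              x$subject_id, x$condition, x$side))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across electrodes from every sample so
#' that each column sums to zero. Average-referenced fields are
#' reference-free, which the global field power and global dissimilarity
#' definitions presuppose; all analysis functions in the package expect
#' average-referenced input and the readers apply this on load.
#'
#' @param x An [eeg_recording] or a channels x samples numeric matrix.
#' @return Object of the same type, average-referenced. Idempotent.
#' @examples
#' apply_average_reference(matrix(c(1, 2, 3), ncol = 1))  # -1 0 1
#' @export
apply_average_reference <- function(x) {
  UseMethod("apply_average_reference")
}

#' @export
apply_average_reference.default <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("average reference needs at least 2 channels")
  sweep(x, 2L, colMeans(x), "-")
}

#' @export
apply_average_reference.eeg_recording <- function(x) {
  x$data <- apply_average_reference.default(x$data)
  x
}

#' Band-pass filter a recording
#'
#' Zero-phase FFT band-pass used as the default pre-processing step
#' (1-40 Hz). Frequency bins outside `[low, high]` are zeroed and the signal
#' reconstructed by the inverse transform, channel by channel. Artifact
#' rejection is deliberately out of scope: recordings are assumed cleaned.
#'
#' @param rec An [eeg_recording].
#' @param low,high Pass-band edges in Hz; `low = 0` disables the high-pass,
#'   `high = Inf` the low-pass.
#' @return Filtered [eeg_recording].
#' @export
bandpass_filter <- function(rec, low = 1, high = 40) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$data)
  freq <- (seq_len(n) - 1L) / n * rec$fs
  freq <- pmin(freq, rec$fs - freq)  # two-sided
  keep <- freq >= low & freq <= high
  keep[1L] <- low <= 0
  filt <- function(v) Re(stats::fft(stats::fft(v) * keep, inverse = TRUE)) / n
  rec$data <- t(apply(rec$data, 1L, filt))
  rownames(rec$data) <- rec$montage$names
  rec
}
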