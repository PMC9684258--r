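#' Backfit microstate templates to a recording
#'
#' Winner-take-all assignment: at every GFP peak the template with the
#' highest absolute spatial correlation to the instantaneous map wins; each
#' sample then takes the label of its nearest peak (interval boundaries at
#' the midpoints between consecutive peaks, edges extended to the recording
#' bounds), and consecutive intervals with the same label are merged into
#' segments. Exact ties in absolute correlation go to the template with the
#' lower label index and are counted in `n_ties`.
#'
#' @param rec An [eeg_recording] on the templates' montage.
#' @param templates A `microstates` fit, `microstate_fit`, or k x channels
#'   template matrix.
#' @param peaks Optional precomputed peak indices; found with default
#'   settings when `NULL`.
#' @param ... Unused.
#' @return Object of class `microstate_sequence`: `peaks`, `winner` (integer
#'   template index per peak), `abs_corr`, `segments` (data.frame: label,
#'   start, end in samples), `labels` (template names), `fs`, `n_samples`,
#'   `n_ties`, `subject_id`, `condition`, `side`.
#' @export
backfit <- function(rec, templates, peaks = NULL, ...) {
  stopifnot(inherits(rec, "eeg_recording"))
  tm <- if (inherits(templates, "microstates")) {
    templates$fit$templates
  } else if (inherits(templates, "microstate_fit")) {
    templates$templates
  } else {
    as.matrix(templates)
  }
  if (ncol(tm) != nrow(rec$data)) stop("template montage does not match recording")
  if (is.null(peaks)) {
    peaks <- find_gfp_peaks(global_field_power(rec))
  }
  peaks <- as.integer(peaks)
  if (length(peaks) < 1L) stop("backfitting needs at least one GFP peak")
  pm <- extract_peak_maps(rec, peaks)
  X <- pm$maps
  Tn <- tm - rowMeans(tm)
  Tn <- Tn / sqrt(rowSums(Tn^2))
  Xn <- X / sqrt(rowSums(X^2))
  A <- abs(Xn %*% t(Tn))
  winner <- max.col(A, ties.method = "first")
  best <- A[cbind(seq_len(nrow(A)), winner)]
  n_ties <- sum(rowSums(abs(A - best) < 1e-12) > 1L)
  n <- ncol(rec$data)
  # nearest-peak midpoint rule
  m <- length(peaks)
  ends <- c(floor((peaks[-m] + peaks[-1L]) / 2), n)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lab <- winner
  keep <- c(TRUE, lab[-1L] != lab[-m])
  seg_start <- starts[keep]
  seg_lab <- lab[keep]
  seg_end <- c(seg_start[-1L] - 1L, n)
  labels <- rownames(tm) %||% paste0("T", seq_len(nrow(tm)))
  structure(list(peaks = peaks, winner = winner, abs_corr = best,
                 segments = data.frame(label = seg_lab, start = seg_start,
                                       end = seg_end),
                 labels = labels, fs = rec$fs, n_samples = n,
                 n_ties = n_ties, subject_id = rec$subject_id,
                 condition = rec$condition, side = rec$side),
            class = "microstate_sequence")
}

#' @export
print.microstate_sequence <- function(x, ...) {
  cat(sprintf("<microstate_sequence> %d peaks, %d segments over %.1f s (%s)\n",
              length(x$peaks), nrow(x$segments), x$n_samples / x$fs,
              paste(x$labels, collapse = " ")))
  invisible(x)
}

#' Microstate metrics from a fitted sequence
#'
#' For every template: mean segment duration (ms), occurrence (segments per
#' second of analyzed time) and coverage (percent of analyzed samples).
#' Templates with no segments get `NA` duration, zero occurrence and zero
#' coverage. Coverages sum to 100 and
#' occurrence x duration / 1000 = coverage / 100 by construction.
#'
#' @param seq A `microstate_sequence` from [backfit].
#' @return data.frame: template, n_segments, mean_duration_ms,
#'   occurrence_hz, coverage_pct.
#' @export
compute_metrics <- function(seq) {
  stopifnot(inherits(seq, "microstate_sequence"))
  segs <- seq$segments
  if (nrow(segs) < 1L) stop("sequence has no segments")
  k <- length(seq$labels)
  lens <- (segs$end - segs$start + 1L) / seq$fs * 1000  # ms
  total_s <- seq$n_samples / seq$fs
  f <- factor(segs$label, levels = seq_len(k))
  nseg <- as.integer(table(f))
  dur <- as.numeric(tapply(lens, f, mean))
  cov <- as.numeric(tapply(lens, f, sum))
  cov[is.na(cov)] <- 0
  data.frame(template = seq$labels,
             n_segments = nseg,
             mean_duration_ms = dur,
             occurrence_hz = nseg / total_s,
             coverage_pct = 100 * cov / (total_s * 1000),
             row.names = NULL)
}

#' Transition probabilities and directional predominance
#'
#' Transitions are counted between consecutive distinct segments; rows are
#' normalized by each template's outgoing transition count (no
#' self-transitions by construction). Directional predominance between X and
#' Y is \eqn{dp(X,Y) = 100 (P(X\to Y) - P(Y\to X))} in percentage points: a
#' positive value means transits from X to Y are the more probable
#' direction. Rows with no outgoing transitions yield undefined
#' probabilities and missing dp.
#'
#' @param seq A `microstate_sequence` with at least two segments.
#' @return List of class `transition_stats`: `counts` (k x k integer), `P`
#'   (row-stochastic, NA rows where undefined), `dp` (k x k antisymmetric,
#'   percentage points), `pairs` (data.frame: from, to, dp for the ordered
#'   pairs with from < to).
#' @export
transition_stats <- function(seq) {
  stopifnot(inherits(seq, "microstate_sequence"))
  labs <- seq$segments$label
  if (length(labs) < 2L) stop("need at least two segments to count transitions")
  k <- length(seq$labels)
  counts <- matrix(0L, k, k, dimnames = list(seq$labels, seq$labels))
  from <- labs[-length(labs)]; to <- labs[-1L]
  for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  out <- rowSums(counts)
  P <- counts / ifelse(out > 0, out, NA_real_)
  dp <- 100 * (P - t(P))
  pairs <- do.call(rbind, lapply(seq_len(k - 1L), function(i) {
    data.frame(from = seq$labels[i], to = seq$labels[(i + 1L):k],
               dp = dp[i, (i + 1L):k])
  }))
  rownames(pairs) <- NULL
  structure(list(counts = counts, P = P, dp = dp, pairs = pairs),
            class = "transition_stats")
}

#' @export
print.transition_stats <- function(x, ...) {
  cat("Transition probabilities:\n")
  print(round(x$P, 3))
  cat("Directional predominance (percentage points):\n")
  print(round(x$dp, 1))
  invisible(x)
}
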