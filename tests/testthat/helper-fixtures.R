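# Shared fixture builders: everything is generated in code at test time.

fixture_montage <- function() standard_montage()

# tiny deterministic recording: given per-sample template index and
# amplitude, build the exact field (no noise)
fixture_recording <- function(labels, amplitudes, templates, fs = 256) {
  data <- t(templates[labels, , drop = FALSE]) *
    rep(amplitudes, each = ncol(templates))
  eeg_recording(data, fs = fs, montage = fixture_montage(),
                subject_id = "fix", condition = "pre", side = "r-TLE")
}

# hand-built microstate sequence (segment runs given in samples)
fixture_sequence <- function(seg_labels, seg_lengths, labels, fs = 1000) {
  ends <- cumsum(seg_lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  structure(list(peaks = as.integer(round((starts + ends) / 2)),
                 winner = seg_labels,
                 abs_corr = rep(1, length(seg_labels)),
                 segments = data.frame(label = seg_labels, start = starts,
                                       end = ends),
                 labels = labels, fs = fs, n_samples = sum(seg_lengths),
                 n_ties = 0L, subject_id = "fix", condition = "pre",
                 side = "r-TLE"),
            class = "microstate_sequence")
}

# brute-force oracle: best explained variance over all bipartitions of maps
brute_force_ev2 <- function(X) {
  X <- X - rowMeans(X)
  n <- nrow(X)
  tot <- sum(X^2)
  best <- -Inf
  for (m in 1:(2^(n - 1L) - 1L)) {
    a <- as.logical(bitwAnd(m, 2^(0:(n - 1L))))
    if (!any(a) || all(a)) next
    l1 <- eigen(crossprod(X[a, , drop = FALSE]), symmetric = TRUE,
                only.values = TRUE)$values[1L]
    l2 <- eigen(crossprod(X[!a, , drop = FALSE]), symmetric = TRUE,
                only.values = TRUE)$values[1L]
    best <- max(best, (l1 + l2) / tot)
  }
  100 * best
}

# null metrics table for the ART calibration designs
null_metrics_table <- function(n_subjects = 27, levels = c("A", "B", "C", "D"),
                               factor_name = "template", base = 70,
                               noise = 7, bd_shift = 0) {
  d <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                   condition = c("pre", "post"), lev = levels,
                   stringsAsFactors = FALSE)
  names(d)[3L] <- factor_name
  d$side <- rep_len(c("l", "r"), n_subjects)[match(d$subject, unique(d$subject))]
  d$value <- base + stats::rnorm(nrow(d), 0, noise)
  if (bd_shift > 0 && factor_name == "template") {
    sel <- d$condition == "post" & d$template %in% c("B", "D")
    d$value[sel] <- d$value[sel] - bd_shift * base
  }
  d
}
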