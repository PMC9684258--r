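# Synthetic resting-state EEG with planted microstate structure. Every
# downstream stage (peak extraction, clustering, model selection, backfitting,
# group statistics) is validated against the ground truth this module plants.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.unit_gfp <- function(maps) {
  # rows = maps; average-reference then scale each to GFP 1 (divisor N)
  maps <- maps - rowMeans(maps)
  g <- sqrt(rowMeans(maps^2))
  if (any(g < 1e-12)) stop("degenerate (zero-GFP) map")
  maps / g
}

#' Canonical microstate reference topographies
#'
#' The four archetypal resting-state maps used for labeling: A (left
#' posterior to right anterior diagonal), B (right posterior to left anterior
#' diagonal), C (anterior-posterior), D (fronto-central maximum). Each is
#' average-referenced with unit GFP.
#'
#' @param montage An [eeg_montage].
#' @return A 4 x channels matrix with rownames `A`..`D`.
#' @export
canonical_templates <- function(montage = standard_montage()) {
  p <- montage$positions
  x <- p[, 1L]; y <- p[, 2L]
  maps <- rbind(
    A = (x + y) / sqrt(2),
    B = (-x + y) / sqrt(2),
    C = y,
    D = 0.8 - (x^2 + (y - 0.2)^2))
  maps <- .unit_gfp(maps)
  colnames(maps) <- montage$names
  maps
}

#' Generate dipolar template maps
#'
#' For `k <= 4` returns the first `k` canonical reference maps
#' ([canonical_templates]); for larger `k`, additional linear dipolar
#' gradients with random orientation and offset are drawn (seeded) under the
#' constraint that all pairwise absolute spatial correlations stay below 0.8.
#'
#' @param montage An [eeg_montage].
#' @param k Number of templates (at most 12).
#' @param seed Integer seed for the extra maps (ignored for `k <= 4`).
#' @return k x channels matrix of unit-GFP average-referenced maps.
#' @export
make_dipolar_templates <- function(montage = standard_montage(), k = 4,
                                   seed = NULL) {
  if (k < 1 || k > 12) stop("k must be in 1..12")
  canon <- canonical_templates(montage)
  if (k <= 4L) return(canon[seq_len(k), , drop = FALSE])
  p <- montage$positions
  .with_seed(seed, {
    maps <- canon
    tries <- 0L
    while (nrow(maps) < k) {
      if ((tries <- tries + 1L) > 2000L) {
        stop("cannot place ", k, " templates with pairwise |corr| < 0.8 ",
             "on this montage")
      }
      ctr <- stats::runif(2, -0.4, 0.4)
      dx <- p[, 1L] - ctr[1L]; dy <- p[, 2L] - ctr[2L]
      a <- stats::rnorm(5)
      cand <- a[1L] * dx + a[2L] * dy +
        a[3L] * dx^2 + a[4L] * dy^2 + a[5L] * dx * dy
      if (sqrt(mean((cand - mean(cand))^2)) < 1e-6) next
      cand <- .unit_gfp(matrix(cand, 1L))
      if (max(abs(stats::cor(t(maps), t(cand)))) < 0.8) {
        maps <- rbind(maps, cand)
      }
    }
    rownames(maps) <- c(rownames(canon), LETTERS[5:12])[seq_len(k)]
    colnames(maps) <- montage$names
    maps
  })
}

#' Simulation configuration
#'
#' Bundles the generator parameters. Defaults reflect eyes-closed
#' alpha-dominant resting EEG as recorded in low-density clinical practice:
#' 19-channel 10/20 montage at 256 Hz, four templates, mean microstate
#' duration 70 ms (middle of the conventional 40-100 ms band), uniform
#' off-diagonal transitions, 10 microvolt peak field amplitude modulated by a
#' rectified 10 Hz sinusoid restarting at each run (so every run carries at
#' least one well-defined GFP peak), and spatially white electrode noise with
#' SD `noise_sigma` relative to the unit-norm template at peak amplitude.
#'
#' @param montage An [eeg_montage].
#' @param fs Sampling rate (Hz).
#' @param duration Recording length (s).
#' @param k_true Number of planted templates.
#' @param templates Optional k x channels matrix; defaults to
#'   [make_dipolar_templates].
#' @param mean_duration_ms Mean run duration per template (scalar or length-k
#'   vector), milliseconds.
#' @param transition k x k row-stochastic matrix with zero diagonal; defaults
#'   to uniform off-diagonal.
#' @param noise_sigma Spatial noise SD relative to unit template norm.
#' @param amplitude_uv Peak field amplitude (microvolts).
#' @param gfp_freq Frequency of the rectified amplitude modulation (Hz).
#' @param run_lengths `"geometric"` (memoryless, matching the mean) or
#'   `"fixed"` (every run exactly `mean_duration_ms`), the latter for exact
#'   hand-checkable fixtures.
#' @param seed Integer seed; identical configurations with identical seeds
#'   yield bit-identical recordings.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(montage = standard_montage(), fs = 256,
                              duration = 60, k_true = 4, templates = NULL,
                              mean_duration_ms = 70, transition = NULL,
                              noise_sigma = 0.3, amplitude_uv = 10,
                              gfp_freq = 10,
                              run_lengths = c("geometric", "fixed"),
                              seed = NULL) {
  run_lengths <- match.arg(run_lengths)
  k <- as.integer(k_true)
  if (is.null(templates)) templates <- make_dipolar_templates(montage, k, seed)
  templates <- as.matrix(templates)
  stopifnot(nrow(templates) == k, ncol(templates) == length(montage$names))
  if (is.null(transition)) {
    transition <- matrix(1 / (k - 1), k, k)
    diag(transition) <- 0
  }
  transition <- as.matrix(transition)
  if (any(abs(diag(transition)) > 1e-12)) stop("transition diagonal must be 0")
  if (any(abs(rowSums(transition) - 1) > 1e-9)) {
    stop("transition rows must sum to 1")
  }
  if (any(apply(transition, 1L, max) <= 0)) {
    stop("transition matrix has an absorbing state")
  }
  mean_duration_ms <- rep_len(mean_duration_ms, k)
  stopifnot(all(mean_duration_ms > 0), fs > 0, duration > 0,
            noise_sigma >= 0)
  structure(list(montage = montage, fs = fs, duration = duration,
                 k_true = k, templates = .unit_gfp(templates),
                 mean_duration_ms = mean_duration_ms,
                 transition = transition, noise_sigma = noise_sigma,
                 amplitude_uv = amplitude_uv, gfp_freq = gfp_freq,
                 run_lengths = run_lengths, seed = seed),
            class = "simulation_config")
}

#' Simulate an EEG recording with planted microstates
#'
#' Draws a semi-Markov label sequence (run lengths geometric with the
#' configured per-template mean, next label from the transition matrix),
#' flips each run's polarity with probability 1/2, modulates the field by a
#' rectified sinusoid restarting at each run, and adds average-referenced
#' spatially white noise. Ground truth (per-sample labels, run table,
#' realized metrics) is returned alongside the recording.
#'
#' @param config A [simulation_config] (or arguments forwarded to it).
#' @param ... Used to build a config when `config` is missing.
#' @return A list of class `microstate_simulation` with elements `recording`
#'   ([eeg_recording]), `truth` (list: `labels`, `signs`, `runs` data.frame,
#'   `templates`, realized `duration_ms`, `occurrence_hz`, `coverage_pct`,
#'   `transition_counts`) and `config`.
#' @examples
#' sim <- simulate_microstates(simulation_config(duration = 2, seed = 1))
#' dim(sim$recording)
#' @export
simulate_microstates <- function(config, ...) {
  if (missing(config)) config <- simulation_config(...)
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, {
    fs <- config$fs
    n <- round(config$duration * fs)
    k <- config$k_true
    mean_len <- config$mean_duration_ms / 1000 * fs  # samples
    # label runs
    lab <- integer(0); len <- integer(0)
    state <- sample.int(k, 1L)
    total <- 0L
    while (total < n) {
      L <- if (config$run_lengths == "geometric") {
        stats::rgeom(1L, 1 / mean_len[state]) + 1L
      } else {
        max(1L, round(mean_len[state]))
      }
      lab <- c(lab, state); len <- c(len, L); total <- total + L
      state <- sample.int(k, 1L, prob = config$transition[state, ])
    }
    len[length(len)] <- len[length(len)] - (total - n)  # truncate last run
    if (len[length(len)] == 0L) { lab <- lab[-length(lab)]; len <- len[-length(len)] }
    starts <- cumsum(c(1L, len[-length(len)]))
    signs <- sample(c(-1, 1), length(lab), replace = TRUE)
    labels <- rep(lab, len)
    sign_s <- rep(signs, len)
    trel <- sequence(len) - 1L
    # Rectified-sinusoid amplitude arch restarting at each run. Runs shorter
    # than one half-period get a single rescaled arch so that every run,
    # however short, carries one well-defined GFP peak (the backfit ground
    # truth is meaningless for runs the peak finder cannot see).
    half <- fs / (2 * config$gfp_freq)
    arch <- pmin(rep(len, len), half)
    amp <- config$amplitude_uv * abs(sin(pi * (trel + 0.5) / arch))
    data <- t(config$templates[labels, , drop = FALSE]) *
      rep(amp * sign_s, each = length(config$montage$names))
    if (config$noise_sigma > 0) {
      noise <- matrix(stats::rnorm(length(data), sd = config$noise_sigma *
                                     config$amplitude_uv),
                      nrow = nrow(data))
      data <- data + apply_average_reference.default(noise)
    }
    rec <- eeg_recording(data, fs = fs, montage = config$montage,
                         subject_id = "sim", condition = NA, side = NA)
    runs <- data.frame(label = lab, start = starts, end = starts + len - 1L,
                       length = len, sign = signs)
    dur <- tapply(runs$length, factor(runs$label, levels = seq_len(k)),
                  mean) / fs * 1000
    occ <- tabulate(runs$label, k) / (n / fs)
    cov <- 100 * tabulate(labels, k) / n
    tc <- matrix(0L, k, k)
    if (nrow(runs) > 1L) {
      for (i in seq_len(nrow(runs) - 1L)) {
        tc[runs$label[i], runs$label[i + 1L]] <- tc[runs$label[i], runs$label[i + 1L]] + 1L
      }
    }
    truth <- list(labels = labels, signs = sign_s, runs = runs,
                  templates = config$templates,
                  duration_ms = as.numeric(dur), occurrence_hz = occ,
                  coverage_pct = cov, transition_counts = tc)
    structure(list(recording = rec, truth = truth, config = config),
              class = "microstate_simulation")
  })
}

#' @export
print.microstate_simulation <- function(x, ...) {
  cat(sprintf("<microstate_simulation> k=%d, %.1f s @ %g Hz, noise %.2f\n",
              x$config$k_true, x$config$duration, x$config$fs,
              x$config$noise_sigma))
  invisible(x)
}

#' Simulate a paired pre/post cohort
#'
#' Generates one recording per subject and condition with shared templates
#' and subject-specific mean durations (log-normal jitter around the base),
#' optionally shortening the durations of templates B and D in the post
#' condition by a fixed fraction — the synthetic analogue of a treatment
#' that destabilizes specific microstates.
#'
#' @param n_subjects Number of subjects (each gets `pre` and `post`).
#' @param duration Per-recording length (s).
#' @param base_duration_ms Cohort-level mean microstate duration (ms).
#' @param subject_cv Coefficient of variation of the per-subject duration.
#' @param bd_reduction Fractional reduction of templates B and D mean
#'   durations in the post condition (0 = null cohort).
#' @param noise_sigma,fs,k Forwarded to [simulation_config].
#' @param seed Integer seed.
#' @return List with `recordings` (list of [eeg_recording] with subject,
#'   condition and side labels), `templates` (the shared truth) and `meta`
#'   (data.frame: subject, condition, side, planted mean durations).
#' @export
simulate_cohort <- function(n_subjects = 27, duration = 60,
                            base_duration_ms = 70, subject_cv = 0.1,
                            bd_reduction = 0, noise_sigma = 0.3, fs = 256,
                            k = 4, seed = 1) {
  montage <- standard_montage()
  templates <- make_dipolar_templates(montage, k)
  sides <- rep(c("r-TLE", "l-TLE"), length.out = n_subjects)
  recordings <- list()
  meta <- NULL
  .with_seed(seed, {
    subj_scale <- exp(stats::rnorm(n_subjects, 0, subject_cv))
    for (s in seq_len(n_subjects)) {
      for (cond in c("pre", "post")) {
        dur <- rep(base_duration_ms * subj_scale[s], k)
        if (cond == "post" && bd_reduction > 0 && k >= 4) {
          dur[c(2L, 4L)] <- dur[c(2L, 4L)] * (1 - bd_reduction)
        }
        cfg <- simulation_config(montage = montage, fs = fs,
                                 duration = duration, k_true = k,
                                 templates = templates,
                                 mean_duration_ms = dur,
                                 noise_sigma = noise_sigma,
                                 seed = seed * 10000L + s * 10L +
                                   (cond == "post"))
        sim <- simulate_microstates(cfg)
        rec <- sim$recording
        rec$subject_id <- sprintf("S%02d", s)
        rec$condition <- cond
        rec$side <- sides[s]
        recordings[[length(recordings) + 1L]] <- rec
        meta <- rbind(meta, data.frame(subject = rec$subject_id,
                                       condition = cond, side = sides[s],
                                       planted_duration_ms = mean(dur)))
      }
    }
  })
  list(recordings = recordings, templates = templates, meta = meta)
}
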