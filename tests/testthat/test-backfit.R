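test_that("midpoint rule tiles the recording between peaks", {
  tpl <- canonical_templates()[1:2, ]
  labels <- rep(1:2, each = 20)
  rec <- fixture_recording(labels, rep(10, 40), tpl)
  sq <- backfit(rec, tpl, peaks = c(10L, 30L))
  expect_equal(sq$segments$label, c(1L, 2L))
  expect_equal(sq$segments$start, c(1L, 21L))
  expect_equal(sq$segments$end, c(20L, 40L))
  expect_error(backfit(rec, tpl, peaks = integer(0)), "at least one")
})

test_that("segments tile without overlap and agree with peak labels", {
  sim <- simulate_microstates(simulation_config(duration = 20, seed = 51,
                                                noise_sigma = 0.2))
  sq <- backfit(sim$recording, sim$truth$templates)
  segs <- sq$segments
  expect_equal(segs$start[1], 1L)
  expect_equal(segs$end[nrow(segs)], sq$n_samples)
  expect_true(all(segs$start[-1] == segs$end[-nrow(segs)] + 1L))
  # every peak lies inside a segment with its own winning label
  seg_of_peak <- findInterval(sq$peaks, segs$start)
  expect_equal(segs$label[seg_of_peak], sq$winner)
})

test_that("noiseless backfitting recovers every peak label", {
  sim <- simulate_microstates(simulation_config(duration = 10, seed = 52,
                                                noise_sigma = 0))
  pk <- find_gfp_peaks(global_field_power(sim$recording))
  sq <- backfit(sim$recording, sim$truth$templates, peaks = pk)
  expect_equal(mean(sq$winner == sim$truth$labels[pk]), 1)
})

test_that("correlation ties go to the lower template index and are flagged", {
  tpl <- canonical_templates()[1:2, ]
  mid <- tpl[1, ] + tpl[2, ]          # equidistant from both templates
  data <- matrix(rep(mid, 5), ncol = 5) * rep(c(1, 5, 1, 5, 1), each = 19)
  rec <- eeg_recording(data, fs = 256)
  sq <- backfit(rec, tpl, peaks = c(2L, 4L))
  expect_true(all(sq$winner == 1L))
  expect_gte(sq$n_ties, 1L)
})

test_that("metrics match the hand-enumerated three-segment fixture", {
  # A:100 ms, B:50 ms, A:150 ms at fs=1000 (300 ms total)
  sq <- fixture_sequence(c(1L, 2L, 1L), c(100L, 50L, 150L),
                         labels = c("A", "B"))
  m <- compute_metrics(sq)
  expect_equal(m$mean_duration_ms, c(125, 50))
  expect_equal(m$occurrence_hz, c(2 / 0.3, 1 / 0.3))
  expect_equal(m$coverage_pct, c(250 / 300 * 100, 50 / 300 * 100))
})

test_that("single-segment metrics are exact", {
  sq <- fixture_sequence(1L, 1000L, labels = c("A", "B"))
  m <- compute_metrics(sq)
  expect_equal(m$mean_duration_ms[1], 1000)
  expect_equal(m$occurrence_hz[1], 1)
  expect_equal(m$coverage_pct[1], 100)
  # absent template: missing duration, zero occurrence and coverage
  expect_true(is.na(m$mean_duration_ms[2]))
  expect_equal(m$occurrence_hz[2], 0)
  expect_equal(m$coverage_pct[2], 0)
})

test_that("metric identities hold on simulated sequences", {
  sim <- simulate_microstates(simulation_config(duration = 30, seed = 53))
  sq <- backfit(sim$recording, sim$truth$templates)
  m <- compute_metrics(sq)
  expect_equal(sum(m$coverage_pct), 100)
  occ_dur <- m$occurrence_hz * m$mean_duration_ms / 1000
  expect_equal(occ_dur, m$coverage_pct / 100, tolerance = 1e-6)
})

test_that("splitting and re-merging a segment leaves metrics unchanged", {
  sq <- fixture_sequence(c(1L, 2L, 1L), c(100L, 50L, 150L),
                         labels = c("A", "B"))
  split <- fixture_sequence(c(1L, 2L, 2L, 1L), c(100L, 20L, 30L, 150L),
                            labels = c("A", "B"))
  # re-merge adjacent same-label segments as backfit would
  segs <- split$segments
  keep <- c(TRUE, segs$label[-1] != segs$label[-nrow(segs)])
  merged <- data.frame(label = segs$label[keep], start = segs$start[keep],
                       end = c(segs$start[keep][-1] - 1L,
                               segs$end[nrow(segs)]))
  split$segments <- merged
  expect_equal(compute_metrics(split), compute_metrics(sq))
})

test_that("transition counts match the hand count and dp is antisymmetric", {
  sq <- fixture_sequence(c(1L, 2L, 1L, 2L, 3L), rep(50L, 5),
                         labels = c("A", "B", "C"))
  ts <- transition_stats(sq)
  expect_equal(ts$P["A", "B"], 1.0)
  expect_equal(ts$P["B", "A"], 0.5)
  expect_equal(ts$dp["A", "B"], 50)
  expect_equal(ts$dp, -t(ts$dp))
  ok <- !is.na(rowSums(ts$P))
  expect_equal(rowSums(ts$P)[ok], c(A = 1, B = 1))
  # C has no outgoing transition: undefined row, missing dp
  expect_true(all(is.na(ts$P["C", ])))
})

test_that("alternating sequences have exactly zero predominance", {
  sq <- fixture_sequence(rep(c(1L, 2L), 10), rep(40L, 20),
                         labels = c("A", "B"))
  ts <- transition_stats(sq)
  expect_equal(ts$dp["A", "B"], 0)
})

test_that("planted durations and transition asymmetry are recovered", {
  Tm <- rbind(c(0, .25, .5, .25), c(1/3, 0, 1/3, 1/3),
              c(.2, .4, 0, .4), c(1/3, 1/3, 1/3, 0))
  sim <- simulate_microstates(simulation_config(duration = 120, seed = 54,
                                                noise_sigma = 0.3,
                                                transition = Tm,
                                                mean_duration_ms = 70))
  sq <- backfit(sim$recording, sim$truth$templates)
  m <- compute_metrics(sq)
  expect_true(all(abs(m$mean_duration_ms - 70) < 12))
  ts <- transition_stats(sq)
  expect_lt(abs(ts$dp["A", "C"] - 30), 8)  # planted 30-point asymmetry
})

test_that("predict on a microstates fit backfits a new recording", {
  co <- simulate_cohort(n_subjects = 1, duration = 15, seed = 55)
  ms <- microstates(co$recordings[[1]], k = 4, n_restarts = 6, seed = 10)
  sq <- predict(ms, co$recordings[[2]])
  expect_s3_class(sq, "microstate_sequence")
  expect_identical(sort(unique(sq$labels)), c("A", "B", "C", "D"))
})
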