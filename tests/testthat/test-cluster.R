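test_that("spatial correlation handles polarity and degenerate maps", {
  tpl <- canonical_templates()
  u <- tpl["A", ]
  expect_equal(polarity_corr(u, u)$r, 1)
  expect_equal(polarity_corr(u, -u)$r, -1)
  expect_equal(polarity_corr(u, -u)$abs, 1)
  # two near-orthogonal difference maps: closed-form Pearson is -1/2
  a <- c(1, -1, rep(0, 17))
  b <- c(0, 1, -1, rep(0, 16))
  expect_equal(polarity_corr(a, b)$r, -0.5)
  expect_error(polarity_corr(rep(0, 19), u), "zero-GFP")
})

test_that("clustering recovers exact templates from noiseless maps", {
  tpl <- canonical_templates()[c("A", "B"), ]
  X <- tpl[rep(1:2, each = 20), ] * sample(c(-1, 1), 40, TRUE) *
    runif(40, 5, 15)
  fit <- cluster_maps(X, 2, n_restarts = 10, seed = 1)
  expect_equal(fit$ev, 100, tolerance = 1e-9)
  r <- abs(stats::cor(t(fit$templates), t(tpl)))
  expect_equal(unname(sort(apply(r, 2, max))), c(1, 1), tolerance = 1e-9)
  expect_equal(fit$W, 0, tolerance = 1e-9)
})

test_that("k = 1 returns the first principal direction of all maps", {
  set.seed(3)
  X <- matrix(rnorm(30 * 19), 30)
  X <- X - rowMeans(X)
  fit <- cluster_maps(X, 1, n_restarts = 1, seed = 2)
  sv <- svd(X)$v[, 1L]  # independent route to the principal direction
  expect_equal(abs(polarity_corr(fit$templates[1, ], sv)$abs), 1,
               tolerance = 1e-8)
  expect_error(cluster_maps(X, 31), "exceeds")
})

test_that("clustering is polarity-invariant", {
  set.seed(9)
  sim <- simulate_microstates(simulation_config(duration = 20, seed = 31))
  pm <- extract_peak_maps(sim$recording,
                          find_gfp_peaks(global_field_power(sim$recording)))
  X <- pm$maps
  flip <- sample(c(-1, 1), nrow(X), TRUE)
  f1 <- cluster_maps(X, 4, n_restarts = 10, seed = 5)
  f2 <- cluster_maps(X * flip, 4, n_restarts = 10, seed = 5)
  expect_equal(f1$ev, f2$ev, tolerance = 1e-9)
  expect_equal(f1$W, f2$W, tolerance = 1e-9)
  r <- abs(stats::cor(t(f1$templates), t(f2$templates)))
  expect_equal(unname(sort(apply(r, 1, max))), rep(1, 4), tolerance = 1e-9)
})

test_that("explained variance grows and dispersion shrinks with k", {
  sim <- simulate_microstates(simulation_config(duration = 20, seed = 32))
  pm <- extract_peak_maps(sim$recording,
                          find_gfp_peaks(global_field_power(sim$recording)))
  evs <- Ws <- numeric(0)
  fit_prev <- NULL
  for (k in 1:6) {
    init <- if (!is.null(fit_prev)) {
      rbind(fit_prev$templates, pm$maps[which.min(fit_prev$abs_corr), ])
    }
    fit_prev <- cluster_maps(pm, k, n_restarts = 10, seed = 40 + k,
                             init = init)
    evs <- c(evs, fit_prev$ev)
    Ws <- c(Ws, fit_prev$W)
  }
  expect_true(all(diff(evs) >= -1e-9))
  expect_true(all(diff(Ws) <= 1e-9))
})

test_that("templates recovered from noisy simulation match the truth", {
  sim <- simulate_microstates(simulation_config(duration = 60, seed = 33,
                                                noise_sigma = 0.3))
  fit <- microstates(sim$recording, k = 4, n_restarts = 8, seed = 6)
  r <- abs(stats::cor(t(coef(fit)), t(sim$truth$templates)))
  # one-to-one: each true template claimed by a distinct recovered one
  expect_true(all(apply(r, 2, max) >= 0.95))
  expect_equal(anyDuplicated(apply(r, 2, which.max)), 0L)
})

test_that("KL criterion finds a constructed sharp elbow", {
  W <- c(1000, 600, 300, 80, 70, 62, 55, 50, 46, 43, 40, 38)
  names(W) <- 1:12
  # independent evaluation of the published formula
  p <- 19
  penal <- (1:12)^(2 / p) * W
  DIFF <- c(NA, -diff(penal))
  KL_ref <- rep(NA_real_, 12)
  for (i in 2:11) KL_ref[i] <- abs(DIFF[i]) / abs(DIFF[i + 1])
  kl <- krzanowski_lai(W, n_features = p)
  expect_equal(kl$KL, KL_ref)
  expect_true(4L %in% kl$local_maxima)
  expect_equal(kl$chosen_k, 4L)
  expect_error(krzanowski_lai(W[1:3], 19), "at least 4")
})

test_that("geometric dispersion has no KL peak and falls back", {
  W <- 0.5^(1:12)
  names(W) <- 1:12
  expect_warning(kl <- krzanowski_lai(W, n_features = 19), "global maximum")
  expect_true(kl$fallback)
  # fallback = global maximum of the independently computed curve
  penal <- (1:12)^(2 / 19) * W
  DIFF <- c(NA, -diff(penal))
  KL_ref <- rep(NA_real_, 12)
  for (i in 2:11) KL_ref[i] <- abs(DIFF[i]) / abs(DIFF[i + 1])
  expect_equal(kl$chosen_k, which.max(KL_ref))
})

test_that("meta-clustering of identical or sign-flipped sets is exact", {
  tpl <- canonical_templates()
  sets <- list(tpl, tpl, tpl * c(-1, 1, -1, 1))
  glob <- meta_cluster(sets, 4, n_restarts = 10, seed = 7)
  r <- abs(stats::cor(t(glob$templates), t(tpl)))
  expect_equal(unname(sort(apply(r, 2, max))), rep(1, 4), tolerance = 1e-9)
  expect_error(meta_cluster(list(tpl, tpl[1:3, ]), 4), "k = 4")
})

test_that("global templates from a simulated cohort match the truth", {
  co <- simulate_cohort(n_subjects = 6, duration = 20, seed = 41)
  indiv <- lapply(co$recordings, function(r) {
    microstates(r, k = 4, n_restarts = 6, seed = 8, label = FALSE)$fit
  })
  glob <- meta_cluster(indiv, 4, n_restarts = 10, seed = 9)
  r <- abs(stats::cor(t(glob$templates), t(co$templates)))
  expect_true(all(apply(r, 2, max) >= 0.97))
})

test_that("canonical labeling is a fixed point and permutation-invariant", {
  tpl <- canonical_templates()
  lab <- canonical_label(tpl)
  expect_identical(rownames(lab), c("A", "B", "C", "D"))
  expect_equal(lab, tpl, tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  lab2 <- canonical_label(tpl[perm, ])
  expect_equal(lab2, tpl, tolerance = 1e-12)
  lab3 <- canonical_label(tpl * c(-1, -1, 1, 1))
  expect_equal(lab3, tpl, tolerance = 1e-12)  # polarity-invariant, reoriented
})

test_that("small-instance clustering attains the brute-force optimum", {
  tpl <- canonical_templates()
  set.seed(50)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    lab <- sample(1:2, n, replace = TRUE)
    X <- tpl[lab, ] * sample(c(-1, 1), n, TRUE) * runif(n, 5, 15) +
      matrix(rnorm(n * 19, 0, runif(1, 1, 8)), n)
    fit <- cluster_maps(X, 2, n_restarts = 50, seed = 60 + i)
    expect_equal(fit$ev, brute_force_ev2(X), tolerance = 1e-8)
  }
})
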