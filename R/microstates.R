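#' Fit a microstate model
#'
#' The package's central fitting function. Takes a recording (or
#' ready-made GFP peak maps), clusters the peak topographies with the
#' polarity-invariant modified k-means, and — when `k` is not fixed — selects
#' the number of templates with the Krzanowski-Lai criterion computed on the
#' within-cluster dispersion curve over `k_range`. The returned object
#' behaves like a classed model fit: `coef()` gives the template matrix,
#' `predict()` backfits new recordings, `plot()` draws the template
#' topographies and `summary()` reports the quality curves.
#'
#' @param x An [eeg_recording], a `peak_maps` object, or a maps x channels
#'   matrix of average-referenced peak topographies.
#' @param k Fixed number of templates; `NULL` (default) selects k by the KL
#'   criterion over `k_range`.
#' @param k_range Candidate k values (contiguous, within 2..12).
#' @param n_restarts Random restarts per k (default 20).
#' @param min_separation_ms,smoothing_ms Peak-detection settings used when
#'   `x` is a recording (see [find_gfp_peaks]).
#' @param label Relabel templates against the canonical A-D maps (default
#'   TRUE when the montage matches the built-in 19-channel set).
#' @param max_maps Cap on the number of peak maps used for the k-range scan;
#'   when exceeded, a seeded random subsample of this size drives model
#'   selection and the final fit at the chosen k still uses all maps.
#' @param max_iter,tol,seed Passed to [cluster_maps].
#' @return An object of class `microstates` with elements `fit` (the chosen
#'   [cluster_maps] fit), `k`, `quality` (data.frame: k, W, ev, KL),
#'   `selection` (KL details or NULL when k was fixed), `peaks`, `call`.
#' @examples
#' sim <- simulate_microstates(simulation_config(duration = 10, seed = 3))
#' ms <- microstates(sim$recording, k = 4, n_restarts = 5, seed = 1)
#' coef(ms)[, 1:3]
#' @export
microstates <- function(x, k = NULL, k_range = 2:12, n_restarts = 20,
                        min_separation_ms = 10, smoothing_ms = 0,
                        label = TRUE, max_maps = 8000, max_iter = 300,
                        tol = 1e-6, seed = NULL) {
  cl <- match.call()
  pm <- NULL
  if (inherits(x, "eeg_recording")) {
    gfp <- global_field_power(x)
    pk <- find_gfp_peaks(gfp, min_separation_ms = min_separation_ms,
                         smoothing_ms = smoothing_ms)
    pm <- extract_peak_maps(x, pk)
  } else if (inherits(x, "peak_maps")) {
    pm <- x
  } else {
    pm <- structure(list(maps = as.matrix(x), peaks = seq_len(nrow(x)),
                         fs = NA_real_, n_samples = nrow(x),
                         montage = NULL, id = NA_character_),
                    class = "peak_maps")
  }
  n_ch <- ncol(pm$maps)
  if (!is.null(k)) {
    fit <- cluster_maps(pm, k, n_restarts = n_restarts, max_iter = max_iter,
                        tol = tol, seed = seed)
    quality <- data.frame(k = k, W = fit$W, ev = fit$ev, KL = NA_real_)
    selection <- NULL
  } else {
    k_range <- sort(unique(as.integer(k_range)))
    if (min(k_range) < 2L || max(k_range) > 12L || any(diff(k_range) != 1L)) {
      stop("k_range must be contiguous within 2..12")
    }
    ks <- c(1L, k_range)  # W(1) anchors the first KL difference
    scan_pm <- pm
    if (nrow(pm$maps) > max_maps) {
      idx <- sort(.with_seed(seed, sample.int(nrow(pm$maps), max_maps)))
      scan_pm$maps <- pm$maps[idx, , drop = FALSE]
      scan_pm$peaks <- pm$peaks[idx]
    }
    fits <- vector("list", length(ks))
    for (i in seq_along(ks)) {
      # warm start: previous solution plus the worst-fitted map as the new
      # seed template; keeps the dispersion curve monotone at modest restarts
      init <- if (i > 1L) {
        prev <- fits[[i - 1L]]
        worst <- scan_pm$maps[which.min(prev$abs_corr), ]
        rbind(prev$templates, worst - mean(worst))
      }
      fits[[i]] <- cluster_maps(scan_pm, ks[i], n_restarts = n_restarts,
                                max_iter = max_iter, tol = tol,
                                seed = if (is.null(seed)) NULL else seed + ks[i],
                                init = init)
    }
    W <- vapply(fits, `[[`, 0, "W")
    names(W) <- ks
    selection <- krzanowski_lai(W, n_features = n_ch)
    chosen <- selection$chosen_k
    if (!chosen %in% k_range) chosen <- max(min(k_range), min(chosen, max(k_range)))
    fit <- if (nrow(scan_pm$maps) < nrow(pm$maps)) {
      cluster_maps(pm, chosen, n_restarts = n_restarts, max_iter = max_iter,
                   tol = tol, seed = if (is.null(seed)) NULL else seed + 999L,
                   init = fits[[match(chosen, ks)]]$templates)
    } else {
      fits[[match(chosen, ks)]]
    }
    quality <- data.frame(k = ks, W = W,
                          ev = vapply(fits, `[[`, 0, "ev"),
                          KL = selection$KL, row.names = NULL)
  }
  if (label && !is.null(pm$montage) &&
      identical(pm$montage$names, standard_montage()$names)) {
    fit <- canonical_label(fit, pm$montage)
  }
  structure(list(fit = fit, k = fit$k, quality = quality,
                 selection = selection, peaks = pm$peaks, fs = pm$fs,
                 montage = pm$montage, call = cl),
            class = "microstates")
}

#' @export
print.microstates <- function(x, ...) {
  cat("Microstate model\n")
  cat(sprintf("  templates: %d (%s)%s\n", x$k,
              paste(x$fit$labels, collapse = " "),
              if (!is.null(x$selection)) " [KL-selected]" else ""))
  cat(sprintf("  peak maps: %d   explained variance: %.1f%%\n",
              x$fit$n_maps, x$fit$ev))
  invisible(x)
}

#' @export
summary.microstates <- function(object, ...) {
  structure(list(k = object$k, labels = object$fit$labels,
                 ev = object$fit$ev, quality = object$quality,
                 selection = object$selection,
                 n_maps = object$fit$n_maps),
            class = "summary.microstates")
}

#' @export
print.summary.microstates <- function(x, ...) {
  cat("Microstate model summary\n")
  cat(sprintf("  chosen k: %d (%s), EV %.1f%% over %d peak maps\n",
              x$k, paste(x$labels, collapse = " "), x$ev, x$n_maps))
  if (!is.null(x$selection)) {
    cat("  quality curves:\n")
    q <- x$quality
    for (i in seq_len(nrow(q))) {
      cat(sprintf("    k=%2d  W=%10.4g  EV=%5.1f%%  KL=%s\n", q$k[i], q$W[i],
                  q$ev[i],
                  ifelse(is.na(q$KL[i]), "   -", sprintf("%7.3f", q$KL[i]))))
    }
    if (x$selection$fallback) {
      cat("  (KL: fewer than two interior local maxima; global maximum used)\n")
    }
  }
  invisible(x)
}

#' @export
coef.microstates <- function(object, ...) object$fit$templates

#' @describeIn backfit `predict` method: backfits the model's templates to a
#'   new recording.
#' @param object A `microstates` fit.
#' @param newdata An [eeg_recording].
#' @export
predict.microstates <- function(object, newdata, peaks = NULL, ...) {
  backfit(newdata, object, peaks = peaks, ...)
}

# inverse-distance-weighted field interpolation for topographic display
.plot_topomap <- function(values, montage, main = "", res = 60) {
  p <- montage$positions
  g <- seq(-1, 1, length.out = res)
  grid <- expand.grid(x = g, y = g)
  inside <- grid$x^2 + grid$y^2 <= 1
  z <- rep(NA_real_, nrow(grid))
  d2 <- outer(grid$x[inside], p[, 1L], "-")^2 +
    outer(grid$y[inside], p[, 2L], "-")^2
  w <- 1 / (d2 + 1e-4)
  z[inside] <- (w %*% values) / rowSums(w)
  pal <- grDevices::hcl.colors(64, "RdBu", rev = TRUE)
  graphics::image(g, g, matrix(z, res, res), col = pal, axes = FALSE,
                  xlab = "", ylab = "", asp = 1, main = main,
                  zlim = max(abs(values)) * c(-1, 1))
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th))
  graphics::lines(c(-0.1, 0, 0.1), c(0.995, 1.08, 0.995))  # nose
  graphics::points(p[, 1L], p[, 2L], pch = 20, cex = 0.5)
}

#' @export
plot.microstates <- function(x, ...) {
  if (is.null(x$montage)) stop("no montage attached; cannot draw topographies")
  k <- x$k
  op <- graphics::par(mfrow = c(1, k), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  for (i in seq_len(k)) {
    .plot_topomap(x$fit$templates[i, ], x$montage, main = x$fit$labels[i])
  }
  invisible(x)
}
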