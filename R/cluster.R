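#' Spatial correlation between two scalp maps
#'
#' Pearson correlation across electrodes of the average-referenced maps.
#' Microstate topographies are polarity-indeterminate, so wherever polarity
#' is irrelevant the absolute value is used.
#'
#' @param u,v Numeric vectors (one potential per electrode, same montage).
#' @return List with `r` (signed correlation) and `abs` (absolute value).
#' @examples
#' m <- canonical_templates()
#' polarity_corr(m["A", ], -m["A", ])  # r = -1, abs = 1
#' @export
polarity_corr <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) stop("maps must share the montage")
  u <- u - mean(u); v <- v - mean(v)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) stop("zero-GFP map has no direction")
  r <- sum(u * v) / (nu * nv)
  list(r = r, abs = abs(r))
}

# First principal direction of a set of maps (rows), i.e. the unit vector
# maximizing the summed squared projections. Sign-indeterminate.
.principal_direction <- function(X) {
  S <- crossprod(X)
  eigen(S, symmetric = TRUE)$vectors[, 1L]
}

#' Polarity-invariant (modified) k-means clustering of peak maps
#'
#' The modified k-means used throughout microstate analysis: each map is
#' assigned to the template with the highest absolute spatial correlation,
#' and each template is updated to the first principal direction of its
#' assigned maps (the orientation-invariant analogue of the cluster mean),
#' renormalized to unit GFP. The best of `n_restarts` random initializations
#' by explained variance is kept.
#'
#' Explained variance is GFP-weighted:
#' \deqn{EV = 100 \sum_i (GFP_i |r_i|)^2 / \sum_i GFP_i^2}
#' with \eqn{r_i} the correlation of map i to its winning template. The
#' within-cluster dispersion reported for model selection is
#' \eqn{W = \sum_i (1 - r_i^2) GFP_i^2}, the orientation-invariant residual.
#'
#' @param maps A `peak_maps` object or a maps x channels numeric matrix
#'   (average-referenced).
#' @param k Number of templates (1 to number of maps).
#' @param n_restarts Random restarts (default 50).
#' @param max_iter Iteration cap per restart.
#' @param tol Relative explained-variance change declaring convergence
#'   (iteration also stops as soon as the assignment is stable).
#' @param seed Optional integer seed (restart initializations).
#' @param init Optional k x channels matrix of starting templates, tried in
#'   addition to the random restarts (used for warm starts across k).
#' @return An object of class `microstate_fit`: list with `templates` (k x
#'   channels, unit GFP), `labels`, `assignment`, `polarity` (sign of the
#'   winning correlation per map), `abs_corr`, `ev` (percent), `W`,
#'   `converged`, `k`, plus bookkeeping fields.
#' @export
cluster_maps <- function(maps, k, n_restarts = 50, max_iter = 300,
                         tol = 1e-6, seed = NULL, init = NULL) {
  pm <- NULL
  if (inherits(maps, "peak_maps")) { pm <- maps; maps <- maps$maps }
  X <- as.matrix(maps)
  X <- X - rowMeans(X)
  n <- nrow(X); C <- ncol(X)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k (", k, ") exceeds the number of maps (", n, ")")
  gfp2 <- rowMeans(X^2)                 # squared GFP per map
  tot <- sum(gfp2)
  rnorm_rows <- sqrt(rowSums(X^2))
  U <- X / rnorm_rows                   # unit-L2 rows; corr = U %*% t(Tn)
  .with_seed(seed, {
    best <- NULL
    starts <- seq_len(n_restarts + !is.null(init))
    for (r in starts) {
      centers <- if (!is.null(init) && r > n_restarts) {
        ini <- as.matrix(init)
        ini / sqrt(rowSums(ini^2))
      } else if (r %% 2L == 1L || k >= n) {
        U[sample.int(n, k), , drop = FALSE]
      } else {
        # partition-based restart: principal directions of a random k-split
        part <- sample.int(k, n, replace = TRUE)
        part[sample.int(n, k)] <- seq_len(k)   # every cluster non-empty
        t(vapply(seq_len(k), function(j) {
          d <- .principal_direction(X[part == j, , drop = FALSE])
          d / sqrt(sum(d^2))
        }, numeric(C)))
      }
      ev_old <- -Inf; converged <- FALSE; iter <- 0L
      assign_old <- integer(0)
      repeat {
        iter <- iter + 1L
        A <- abs(U %*% t(centers))      # n x k absolute correlations
        assign_ <- max.col(A, ties.method = "first")
        for (j in seq_len(k)) {
          idx <- which(assign_ == j)
          if (length(idx) == 0L) {      # re-seed empty cluster at worst map
            idx <- which.min(A[cbind(seq_len(n), assign_)])
            assign_[idx] <- j
          }
          d <- .principal_direction(X[idx, , drop = FALSE])
          centers[j, ] <- d / sqrt(sum(d^2))
        }
        A <- abs(U %*% t(centers))
        assign_ <- max.col(A, ties.method = "first")
        ac <- A[cbind(seq_len(n), assign_)]
        ev <- sum(gfp2 * ac^2) / tot
        if (identical(assign_, assign_old) ||
            abs(ev - ev_old) <= tol * max(ev_old, .Machine$double.eps)) {
          converged <- TRUE
          break
        }
        if (iter >= max_iter) break
        ev_old <- ev
        assign_old <- assign_
      }
      if (is.null(best) || ev > best$ev) {
        best <- list(centers = centers, assignment = assign_, abs_corr = ac,
                     ev = ev, converged = converged, iter = iter)
      }
    }
    if (!best$converged) {
      warning("modified k-means did not converge in ", max_iter,
              " iterations; returning best iterate")
    }
    signed <- (U %*% t(best$centers))[cbind(seq_len(n), best$assignment)]
    templates <- .unit_gfp(best$centers)
    rownames(templates) <- paste0("T", seq_len(k))
    if (!is.null(colnames(X))) colnames(templates) <- colnames(X)
    W <- sum(gfp2 * (1 - best$abs_corr^2))
    structure(list(templates = templates,
                   labels = rownames(templates),
                   assignment = best$assignment,
                   polarity = ifelse(signed >= 0, 1, -1),
                   abs_corr = best$abs_corr,
                   ev = 100 * best$ev, W = W, k = k,
                   converged = best$converged,
                   n_maps = n, montage = pm$montage,
                   provenance = "individual"),
              class = "microstate_fit")
  })
}

#' @export
print.microstate_fit <- function(x, ...) {
  cat(sprintf("<microstate_fit> k=%d templates (%s), %d maps, EV %.1f%%\n",
              x$k, paste(x$labels, collapse = " "), x$n_maps, x$ev))
  invisible(x)
}

#' Krzanowski-Lai criterion for the number of templates
#'
#' From within-cluster dispersions \eqn{W(k)} over a contiguous range of k,
#' computes \eqn{DIFF(k) = (k-1)^{2/p} W(k-1) - k^{2/p} W(k)} with p the
#' feature dimensionality (number of electrodes) and
#' \eqn{KL(k) = |DIFF(k)| / |DIFF(k+1)|}.
#'
#' The conventional reading of "the second KL maximum" skips the trivial
#' first maximum that the raw curve exhibits at its small-k boundary. Here
#' that cleaning is explicit: boundary values of the defined curve are never
#' peaks, and k where the penalized dispersion no longer improves
#' (\eqn{DIFF(k) \le 0}) are discarded, because ratios of the near-zero
#' differences past the elbow produce arbitrarily large spurious KL values.
#' The optimal k is the largest remaining interior local maximum; when none
#' exists the global maximum over the improving k is used (with a warning
#' and `fallback = TRUE` in the result).
#'
#' @param W Named numeric vector of dispersions; names are the k values,
#'   which must be contiguous integers (at least 4 of them).
#' @param n_features Feature dimensionality p (electrode count).
#' @return List with `k_values`, `KL` (NA where undefined), `DIFF`,
#'   `chosen_k`, `local_maxima` and `fallback`.
#' @export
krzanowski_lai <- function(W, n_features) {
  ks <- as.integer(names(W))
  if (is.null(ks) || anyNA(ks)) ks <- seq_along(W)
  if (length(ks) < 4L) stop("need W for at least 4 consecutive k values")
  if (any(diff(ks) != 1L)) stop("k values must be contiguous")
  p <- n_features
  penal <- ks^(2 / p) * W
  DIFF <- c(NA, diff(-penal))           # DIFF(k) = penal(k-1) - penal(k)
  KL <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    if (i > 1L && i < length(ks) && abs(DIFF[i + 1L]) > 1e-300) {
      KL[i] <- abs(DIFF[i]) / abs(DIFF[i + 1L])
    }
  }
  defined <- which(!is.na(KL))
  # strict local maxima of the KL curve (interior to the defined range),
  # kept only where the penalized dispersion still improves (DIFF > 0)
  lm_idx <- defined[vapply(defined, function(i) {
    left <- if ((i - 1L) %in% defined) KL[i] > KL[i - 1L] else TRUE
    right <- if ((i + 1L) %in% defined) KL[i] > KL[i + 1L] else TRUE
    left && right
  }, logical(1L))]
  lm_idx <- setdiff(lm_idx, range(defined))
  lm_idx <- lm_idx[DIFF[lm_idx] > 0]
  ok <- defined[DIFF[defined] > 0]
  if (length(ok) == 0L) ok <- defined
  fallback <- length(lm_idx) == 0L
  chosen <- if (length(lm_idx) >= 1L) {
    ks[lm_idx[which.max(KL[lm_idx])]]
  } else {
    warning("KL curve has no interior local maximum; using its global maximum")
    ks[ok[which.max(KL[ok])]]
  }
  list(k_values = ks, KL = KL, DIFF = DIFF, chosen_k = chosen,
       local_maxima = ks[lm_idx], fallback = fallback)
}

#' Meta-cluster individual template sets into global templates
#'
#' Pools the individual (per-recording) templates — each already unit-GFP —
#' and reruns the polarity-invariant clustering on the pooled maps with the
#' same k, the spatial-correlation second clustering level that yields the
#' global template set.
#'
#' @param sets List of `microstate_fit` objects or k x channels matrices,
#'   all with the same k and montage.
#' @param k Number of global templates; must equal each set's k.
#' @param ... Passed to [cluster_maps].
#' @return A `microstate_fit` with provenance `"global"`.
#' @export
meta_cluster <- function(sets, k, ...) {
  mats <- lapply(sets, function(s) {
    if (inherits(s, "microstate_fit")) s$templates else as.matrix(s)
  })
  ks <- vapply(mats, nrow, 0L)
  if (any(ks != k)) {
    stop("all template sets must have k = ", k, " templates (found: ",
         paste(unique(ks), collapse = ", "), ")")
  }
  nc <- vapply(mats, ncol, 0L)
  if (length(unique(nc)) != 1L) stop("template sets are on different montages")
  pooled <- do.call(rbind, mats)
  fit <- cluster_maps(pooled, k, ...)
  fit$provenance <- "global"
  fit
}

#' Label templates against the canonical A-D maps
#'
#' Greedy one-to-one matching of templates to the built-in canonical
#' reference maps ([canonical_templates]) by absolute spatial correlation,
#' highest first. Matched templates are renamed A-D, reordered into label
#' order and sign-oriented to correlate positively with their canonical map;
#' templates beyond the four canonical shapes keep their relative order and
#' get labels E, F, ...
#'
#' @param x A `microstate_fit` or a k x channels template matrix.
#' @param montage Montage for the canonical maps (defaults to 10/20-19).
#' @return Object of the same type, relabeled and reordered.
#' @export
canonical_label <- function(x, montage = standard_montage()) {
  tm <- if (inherits(x, "microstate_fit")) x$templates else as.matrix(x)
  canon <- canonical_templates(montage)
  if (ncol(tm) != ncol(canon)) stop("template montage does not match")
  k <- nrow(tm)
  R <- stats::cor(t(canon), t(tm))          # 4 x k signed correlations
  n_match <- min(4L, k)
  lab <- rep(NA_character_, k)
  sgn <- rep(1, k)
  Rw <- abs(R)
  for (m in seq_len(n_match)) {
    ij <- which(Rw == max(Rw), arr.ind = TRUE)[1L, ]
    lab[ij[2L]] <- rownames(canon)[ij[1L]]
    sgn[ij[2L]] <- sign(R[ij[1L], ij[2L]])
    Rw[ij[1L], ] <- -Inf
    Rw[, ij[2L]] <- -Inf
  }
  if (k > 4L) lab[is.na(lab)] <- LETTERS[5:26][seq_len(k - 4L)]
  ord <- order(lab)
  tm <- tm * sgn
  tm <- tm[ord, , drop = FALSE]
  rownames(tm) <- lab[ord]
  if (inherits(x, "microstate_fit")) {
    x$templates <- tm
    x$labels <- lab[ord]
    # remap assignments to the new template order
    remap <- match(seq_len(k), ord)
    x$assignment <- remap[x$assignment]
    x$polarity <- x$polarity * sgn[ord][x$assignment]
    x
  } else {
    tm
  }
}
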