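#' Global map dissimilarity
#'
#' Reference-independent distance between two scalp fields after GFP
#' normalization:
#' \deqn{GD_{u,v} = \sqrt{\frac{1}{N}\sum_i (u_i/GFP_u - v_i/GFP_v)^2}}
#' with GFP the population (divisor N) standard deviation across electrodes.
#' For average-referenced maps \eqn{GD^2 = 2(1 - r)} with r the spatial
#' correlation, so GD ranges from 0 (identical topography) to 2 (inverted
#' topography).
#'
#' @param u,v Average-referenced maps on the same montage, nonzero GFP.
#' @return The dissimilarity (scalar in `[0, 2]`).
#' @examples
#' m <- canonical_templates()
#' global_dissimilarity(m["A", ], -m["A", ])  # 2
#' @export
global_dissimilarity <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) stop("maps must share the montage")
  u <- u - mean(u); v <- v - mean(v)
  gu <- sqrt(mean(u^2)); gv <- sqrt(mean(v^2))
  if (gu < 1e-12 || gv < 1e-12) stop("zero-GFP map has no topography")
  sqrt(mean((u / gu - v / gv)^2))
}

#' Permutation TANOVA for paired condition maps
#'
#' Topographic analysis of variance: tests whether the mean topography
#' differs between two paired conditions. Because microstate templates are
#' polarity-indeterminate, every map is first sign-aligned to the first map
#' of `group_u`. The observed statistic is the global dissimilarity between
#' the two condition mean maps (each average-referenced and renormalized);
#' the null distribution is built by randomly swapping the two condition
#' maps within each subject pair. The p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{GD^* \ge GD\}) / (1 + n_{perm})}, so it can never be 0.
#'
#' @param group_u,group_v Subjects x channels matrices of per-subject maps,
#'   one row per subject, rows paired across the two matrices.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Optional integer seed.
#' @return List of class `tanova`: `gd` (observed), `p`, `n_perm`, `perm_gd`.
#' @export
tanova <- function(group_u, group_v, n_perm = 999, seed = NULL) {
  U <- as.matrix(group_u); V <- as.matrix(group_v)
  if (!all(dim(U) == dim(V))) {
    stop("groups must be paired: equal subject and channel counts")
  }
  if (n_perm < 99) stop("use at least 99 permutations")
  n <- nrow(U)
  U <- U - rowMeans(U); V <- V - rowMeans(V)
  ref <- U[1L, ]
  align <- function(M) {
    s <- sign(M %*% ref)
    s[s == 0] <- 1
    M * as.numeric(s)
  }
  U <- align(U); V <- align(V)
  stat <- function(Umat, Vmat) {
    global_dissimilarity(colMeans(Umat), colMeans(Vmat))
  }
  observed <- stat(U, V)
  .with_seed(seed, {
    perm_gd <- vapply(seq_len(n_perm), function(i) {
      flip <- stats::runif(n) < 0.5
      Up <- U; Vp <- V
      Up[flip, ] <- V[flip, ]
      Vp[flip, ] <- U[flip, ]
      stat(Up, Vp)
    }, 0)
    p <- (1 + sum(perm_gd >= observed)) / (1 + n_perm)
    structure(list(gd = observed, p = p, n_perm = n_perm, perm_gd = perm_gd),
              class = "tanova")
  })
}

#' @export
print.tanova <- function(x, ...) {
  cat(sprintf("TANOVA: observed GD = %.4f, p = %.4g (%d permutations)\n",
              x$gd, x$p, x$n_perm))
  invisible(x)
}

#' TANOVA across a set of matched templates
#'
#' Runs [tanova] once per template label and additionally reports a global
#' test whose statistic is the mean observed GD across templates, evaluated
#' against the same subject-wise swap permutations.
#'
#' @param sets_u,sets_v Named lists (one element per template label) of
#'   subjects x channels matrices, paired across conditions.
#' @param n_perm,seed As in [tanova].
#' @return List of class `tanova_set`: per-template `gd` and `p` (named),
#'   plus `global_gd` and `global_p`.
#' @export
tanova_templates <- function(sets_u, sets_v, n_perm = 999, seed = NULL) {
  stopifnot(length(sets_u) == length(sets_v))
  labels <- names(sets_u) %||% paste0("T", seq_along(sets_u))
  res <- lapply(seq_along(sets_u), function(i) {
    tanova(sets_u[[i]], sets_v[[i]], n_perm = n_perm,
           seed = if (is.null(seed)) NULL else seed + i)
  })
  gd <- vapply(res, `[[`, 0, "gd")
  p <- vapply(res, `[[`, 0, "p")
  names(gd) <- names(p) <- labels
  perm_mean <- rowMeans(vapply(res, `[[`, numeric(n_perm), "perm_gd"))
  global_gd <- mean(gd)
  global_p <- (1 + sum(perm_mean >= global_gd)) / (1 + n_perm)
  structure(list(gd = gd, p = p, global_gd = global_gd, global_p = global_p,
                 n_perm = n_perm),
            class = "tanova_set")
}

#' @export
print.tanova_set <- function(x, ...) {
  for (l in names(x$gd)) {
    cat(sprintf("  template %s: GD = %.4f, p = %.4g\n", l, x$gd[l], x$p[l]))
  }
  cat(sprintf("  global: mean GD = %.4f, p = %.4g\n", x$global_gd, x$global_p))
  invisible(x)
}
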