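# Aligned rank transform (ART) factorial ANOVA and ART-C contrasts for
# nonparametric repeated-measures designs, plus the contingency chi-square
# used for clinical characteristics.

.check_cells <- function(data, factors) {
  cells <- interaction(data[factors], drop = FALSE, sep = ":")
  empty <- setdiff(levels(cells), levels(droplevels(cells)))
  if (length(empty) > 0L) {
    stop("design has empty cell(s): ", paste(empty, collapse = ", "))
  }
  invisible(cells)
}

# Finite-factorial effect estimate at each observation for the factor subset
# `effect`: inclusion-exclusion over marginal means of its sub-subsets.
.effect_estimate <- function(y, data, effect) {
  est <- rep(0, length(y))
  subsets <- unlist(lapply(0:length(effect), function(m) {
    utils::combn(effect, m, simplify = FALSE)
  }), recursive = FALSE)
  for (S in subsets) {
    mu <- if (length(S) == 0L) {
      rep(mean(y), length(y))
    } else {
      stats::ave(y, data[S])
    }
    est <- est + (-1)^(length(effect) - length(S)) * mu
  }
  est
}

#' Align and rank a response for one effect
#'
#' The alignment step of the aligned rank transform: the response is
#' stripped to residual + target-effect estimate (all other effects'
#' marginal estimates subtracted via the full-crossing cell means), then
#' converted to midranks. An ANOVA on the result isolates the target effect.
#'
#' @param data A data.frame in long format.
#' @param response Name of the numeric response column.
#' @param factors Character vector of factor columns forming the full
#'   factorial design.
#' @param effect Character vector: the target main effect (length 1) or
#'   interaction (length > 1); must be a subset of `factors`.
#' @return Numeric vector of aligned midranks, one per row of `data`.
#' @export
art_align_and_rank <- function(data, response, factors, effect) {
  stopifnot(all(effect %in% factors), response %in% names(data))
  for (f in factors) data[[f]] <- factor(data[[f]])
  .check_cells(data, factors)
  y <- data[[response]]
  if (any(!is.finite(y))) stop("response contains non-finite values")
  cellmean <- stats::ave(y, data[factors])
  aligned <- y - cellmean + .effect_estimate(y, data, effect)
  rank(aligned, ties.method = "average")
}

.all_effects <- function(factors) {
  unlist(lapply(seq_along(factors), function(m) {
    utils::combn(factors, m, simplify = FALSE)
  }), recursive = FALSE)
}

#' ART factorial ANOVA
#'
#' For each requested effect the response is aligned and midranked
#' ([art_align_and_rank]) and a full-factorial ANOVA with a single residual
#' error stratum is fitted on the ranks; only the target effect's F ratio is
#' read from each fit. With a complete factorial on n observations the
#' denominator df is n minus the number of factorial cells, which for the
#' 27-subject two-condition four-template design gives F(1, 208) for the
#' Condition effect (216 observations, 8 cells).
#'
#' Covariates enter as additional crossing factors (between-subject strata),
#' not as continuous regressors.
#'
#' @param data Long-format data.frame.
#' @param response Numeric response column name.
#' @param factors Character vector of factor columns (full factorial).
#' @param effects List of character vectors selecting effects to test;
#'   default all main effects and interactions of `factors`.
#' @return Object of class `art_anova`: data.frame `table` with columns
#'   effect, df1, df2, F, p, plus the call ingredients.
#' @export
art_anova <- function(data, response, factors, effects = NULL) {
  for (f in factors) data[[f]] <- factor(data[[f]])
  .check_cells(data, factors)
  if (is.null(effects)) effects <- .all_effects(factors)
  form <- stats::as.formula(paste(".rank__ ~", paste(factors, collapse = "*")))
  rows <- lapply(effects, function(eff) {
    data$.rank__ <- art_align_and_rank(data, response, factors, eff)
    fit <- stats::aov(form, data = data)
    tab <- summary(fit)[[1L]]
    term <- paste(eff, collapse = ":")
    rn <- trimws(rownames(tab))
    i <- match(term, rn)
    if (is.na(i)) {  # interaction terms may be listed in a different order
      i <- which(vapply(strsplit(rn, ":"), function(s) {
        setequal(s, eff)
      }, logical(1L)))[1L]
    }
    if (is.na(i)) stop("effect not found in ANOVA table: ", term)
    data.frame(effect = term, df1 = tab$Df[i],
               df2 = tab$Df[nrow(tab)], F = tab$`F value`[i],
               p = tab$`Pr(>F)`[i], stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows), response = response,
                 factors = factors, data = data),
            class = "art_anova")
}

#' @export
print.art_anova <- function(x, ...) {
  cat("ART ANOVA on", x$response, "\n")
  t <- x$table
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-30s F(%d, %d) = %.2f, p = %.4g\n",
                t$effect[i], t$df1[i], t$df2[i], t$F[i], t$p[i]))
  }
  invisible(x)
}

#' ART-C multifactor contrasts
#'
#' Contrast testing on aligned ranks following the ART-C recipe: the levels
#' of the factors involved in the contrast are concatenated into a single
#' factor, the response is aligned and ranked for that combined factor, and
#' pairwise t statistics are computed from the combined-factor cell means
#' with the pooled residual variance of the one-way fit on ranks. Family
#' p-values are Bonferroni adjusted (`p_adj = min(1, m p)`).
#'
#' @param data Long-format data.frame.
#' @param response Numeric response column name.
#' @param factors All factorial columns (for the alignment cell means).
#' @param effect Factors whose level combinations are contrasted.
#' @param pairs Either `"pairwise"` (all combined-level pairs) or a list of
#'   length-2 character vectors of combined levels (levels joined by ":").
#' @return data.frame of class `art_contrasts`: contrast, estimate (rank
#'   mean difference), t, df, p_raw, p_adj.
#' @export
art_c_contrasts <- function(data, response, factors, effect,
                            pairs = "pairwise") {
  for (f in factors) data[[f]] <- factor(data[[f]])
  .check_cells(data, factors)
  combined <- interaction(data[effect], sep = ":", drop = TRUE)
  y <- data[[response]]
  cellmean <- stats::ave(y, data[factors])
  aligned <- y - cellmean + (stats::ave(y, combined) - mean(y)) + mean(y)
  r <- rank(aligned, ties.method = "average")
  lev <- levels(combined)
  ncell <- as.integer(table(combined))
  mu <- tapply(r, combined, mean)
  # pooled residual variance of the one-way fit on ranks
  sse <- sum((r - stats::ave(r, combined))^2)
  dfres <- length(r) - length(lev)
  s2 <- sse / dfres
  if (identical(pairs, "pairwise")) {
    pairs <- utils::combn(lev, 2L, simplify = FALSE)
  }
  bad <- setdiff(unlist(pairs), lev)
  if (length(bad) > 0L) {
    stop("contrast references absent level(s): ", paste(bad, collapse = ", "))
  }
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    i <- match(pr[1L], lev); j <- match(pr[2L], lev)
    est <- mu[i] - mu[j]
    se <- sqrt(s2 * (1 / ncell[i] + 1 / ncell[j]))
    tval <- est / se
    p <- 2 * stats::pt(-abs(tval), dfres)
    data.frame(contrast = paste(pr, collapse = " - "), estimate = est,
               t = tval, df = dfres, p_raw = p,
               p_adj = min(1, m * p), stringsAsFactors = FALSE,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("art_contrasts", "data.frame")
  out
}

#' Pearson chi-square for a contingency table
#'
#' Plain Pearson chi-square without continuity correction, as used for
#' comparing clinical characteristics between outcome groups.
#'
#' @param counts Matrix of nonnegative integer counts.
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
chi_square_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero marginal")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}
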