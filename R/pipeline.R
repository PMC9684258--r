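# End-to-end study workflow: peak extraction, per-recording clustering,
# per-condition meta-clustering, KL selection, TANOVA between condition-wise
# template sets, pooled global templates, backfitting, metrics, ART reports.

#' Run the full microstate pipeline
#'
#' Orchestrates the study workflow over a cohort of paired recordings. For
#' every subject and condition the GFP peak maps are clustered; the number
#' of templates is selected per recording by the Krzanowski-Lai criterion
#' and the cohort-level k is the modal choice. Per-condition global
#' templates are then obtained by meta-clustering the individual sets at
#' that k, compared across conditions with a permutation TANOVA, and — when
#' the TANOVA finds no difference — pooled into one global set used to
#' backfit every recording. Metrics (duration, occurrence, coverage,
#' directional predominance) feed the ART ANOVA designs. When the TANOVA is
#' significant for any template, condition-wise sets are kept and each
#' condition is backfitted with its own set (`split_templates = TRUE` in the
#' result).
#'
#' @param recordings Either a data.frame manifest with columns `subject`,
#'   `condition` (`"pre"`/`"post"`), `side`, `path` (files readable by
#'   [read_recording]), or a named list of [eeg_recording] objects carrying
#'   those labels.
#' @param k Fixed template count; `NULL` selects it by KL.
#' @param k_range Candidate k values when selecting.
#' @param n_restarts Restarts for every clustering call.
#' @param n_perm TANOVA permutations.
#' @param alpha TANOVA significance level for the pooling decision.
#' @param out_dir Optional output directory; when given, templates (TSV),
#'   quality curves (JSON), TANOVA (JSON), metrics (TSV) and ART tables
#'   (JSON) are written there with a provenance block (seed, parameters).
#' @param seed Integer seed governing every stochastic step.
#' @return List of class `microstate_pipeline`: `k`, `templates` (global
#'   `microstate_fit`), `condition_templates`, `tanova`, `metrics`
#'   (long-format data.frame), `transitions`, `art` (list of `art_anova`),
#'   `split_templates`, `provenance`.
#' @export
run_pipeline <- function(recordings, k = NULL, k_range = 2:12,
                         n_restarts = 10, n_perm = 999, alpha = 0.05,
                         out_dir = NULL, seed = 1) {
  recs <- .load_manifest(recordings)
  meta <- data.frame(
    subject = vapply(recs, function(r) r$subject_id, ""),
    condition = vapply(recs, function(r) r$condition, ""),
    side = vapply(recs, function(r) r$side, ""),
    stringsAsFactors = FALSE)
  .check_manifest(meta)
  conditions <- c("pre", "post")

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[pipeline] %-22s %6.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  pmaps <- stage("gfp_peaks", lapply(recs, function(r) {
    extract_peak_maps(r, find_gfp_peaks(global_field_power(r)))
  }))

  if (is.null(k)) {
    sel <- stage("kl_selection", lapply(seq_along(pmaps), function(i) {
      ms <- microstates(pmaps[[i]], k = NULL, k_range = k_range,
                        n_restarts = n_restarts, label = FALSE,
                        seed = seed + i)
      ms$k
    }))
    kk <- unlist(sel)
    k <- as.integer(names(sort(table(kk), decreasing = TRUE))[1L])
  }

  indiv <- stage("individual_clustering", lapply(seq_along(pmaps), function(i) {
    cluster_maps(pmaps[[i]], k, n_restarts = n_restarts, seed = seed + 1000L + i)
  }))

  cond_fit <- stage("meta_clustering", {
    lapply(stats::setNames(conditions, conditions), function(cond) {
      canonical_label(
        meta_cluster(indiv[meta$condition == cond], k,
                     n_restarts = n_restarts,
                     seed = seed + match(cond, conditions)))
    })
  })

  tano <- stage("tanova", {
    subjects <- unique(meta$subject)
    per_label <- lapply(stats::setNames(conditions, conditions), function(cond) {
      glob <- cond_fit[[cond]]$templates
      sets <- lapply(rownames(glob), function(lb) {
        t(vapply(subjects, function(s) {
          f <- indiv[[which(meta$subject == s & meta$condition == cond)]]
          r <- abs(stats::cor(t(f$templates), glob[lb, ]))
          f$templates[which.max(r), ]
        }, numeric(ncol(glob))))
      })
      names(sets) <- rownames(glob)
      sets
    })
    common <- intersect(names(per_label$pre), names(per_label$post))
    tanova_templates(per_label$pre[common], per_label$post[common],
                     n_perm = n_perm, seed = seed + 77L)
  })

  split_templates <- any(tano$p < alpha)
  global_fit <- stage("global_templates", {
    if (split_templates) {
      NULL
    } else {
      canonical_label(meta_cluster(indiv, k, n_restarts = n_restarts,
                                   seed = seed + 3L))
    }
  })

  seqs <- stage("backfit", lapply(seq_along(recs), function(i) {
    tm <- if (split_templates) cond_fit[[meta$condition[i]]] else global_fit
    backfit(recs[[i]], tm, peaks = pmaps[[i]]$peaks)
  }))

  metrics <- stage("metrics", {
    do.call(rbind, lapply(seq_along(seqs), function(i) {
      m <- compute_metrics(seqs[[i]])
      cbind(meta[rep(i, nrow(m)), , drop = FALSE], m, row.names = NULL)
    }))
  })
  transitions <- stage("transitions", {
    do.call(rbind, lapply(seq_along(seqs), function(i) {
      tr <- transition_stats(seqs[[i]])
      cbind(meta[rep(i, nrow(tr$pairs)), , drop = FALSE], tr$pairs,
            pair = paste0(tr$pairs$from, tr$pairs$to), row.names = NULL)
    }))
  })

  art <- stage("art_anova", {
    res <- list()
    for (metric in c("mean_duration_ms", "occurrence_hz", "coverage_pct")) {
      d <- metrics[, c("subject", "condition", "side", "template", metric)]
      names(d)[5L] <- "value"
      res[[metric]] <- art_anova(d, "value", c("condition", "template"))
    }
    dtr <- transitions[, c("subject", "condition", "side", "pair", "dp")]
    if (!anyNA(dtr$dp)) {
      res$directional_predominance <-
        art_anova(dtr, "dp", c("condition", "pair"))
    }
    res
  })

  prov <- list(seed = seed, k = k, n_restarts = n_restarts, n_perm = n_perm,
               alpha = alpha, n_recordings = length(recs),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  out <- structure(list(k = k, templates = global_fit,
                        condition_templates = cond_fit, tanova = tano,
                        metrics = metrics, transitions = transitions,
                        art = art, split_templates = split_templates,
                        sequences = seqs, provenance = prov),
                   class = "microstate_pipeline")
  if (!is.null(out_dir)) .write_bundle(out, out_dir)
  out
}

#' @export
print.microstate_pipeline <- function(x, ...) {
  cat("Microstate pipeline result\n")
  cat(sprintf("  k = %d; TANOVA global p = %.3g; %s templates\n", x$k,
              x$tanova$global_p,
              if (x$split_templates) "condition-wise" else "pooled global"))
  cat(sprintf("  metrics rows: %d; ART models: %s\n", nrow(x$metrics),
              paste(names(x$art), collapse = ", ")))
  invisible(x)
}

.load_manifest <- function(recordings) {
  if (is.data.frame(recordings)) {
    need <- c("subject", "condition", "side", "path")
    if (!all(need %in% names(recordings))) {
      stop("manifest needs columns: ", paste(need, collapse = ", "))
    }
    lapply(seq_len(nrow(recordings)), function(i) {
      r <- read_recording(recordings$path[i])
      r$subject_id <- as.character(recordings$subject[i])
      r$condition <- as.character(recordings$condition[i])
      r$side <- as.character(recordings$side[i])
      r
    })
  } else if (is.list(recordings) &&
             all(vapply(recordings, inherits, TRUE, "eeg_recording"))) {
    recordings
  } else {
    stop("'recordings' must be a manifest data.frame or a list of eeg_recording")
  }
}

.check_manifest <- function(meta) {
  for (s in unique(meta$subject)) {
    have <- meta$condition[meta$subject == s]
    miss <- setdiff(c("pre", "post"), have)
    if (length(miss) > 0L) {
      stop("subject ", s, " lacks condition(s): ", paste(miss, collapse = ", "))
    }
  }
}

.write_bundle <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wj <- function(obj, file) {
    jsonlite::write_json(obj, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(x$templates)) {
    utils::write.table(t(x$templates$templates),
                       file.path(out_dir, "global_templates.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  wj(list(gd = as.list(x$tanova$gd), p = as.list(x$tanova$p),
          global_gd = x$tanova$global_gd, global_p = x$tanova$global_p),
     "tanova.json")
  utils::write.table(x$metrics, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$transitions, file.path(out_dir, "transitions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  wj(lapply(x$art, function(a) a$table), "art.json")
  wj(x$provenance, "provenance.json")
  invisible(NULL)
}
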