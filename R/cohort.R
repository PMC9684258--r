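#' Load a patient cohort table
#'
#' Reads the tab-delimited cohort description used for group statistics: one
#' row per patient with sex, age at diagnosis (years), seizure-frequency
#' category, semiology, aetiology, EEG focus, clinical outcome, levetiracetam
#' maintenance dose (mg) and adverse events. The packaged fixture
#' (`cohort_tle_lev.tsv`) describes the 27-patient newly diagnosed temporal
#' lobe epilepsy cohort the package's statistical designs are sized for.
#'
#' Outcome codes: `SF` seizure-free, `NSF>50` / `NSF<50` non-seizure-free
#' with more / less than 50% seizure reduction.
#'
#' @param path Path to a cohort TSV; defaults to the packaged fixture.
#' @return A `data.frame` of class `cohort_table` with typed columns and the
#'   derived logicals `structural` (structural aetiology) and `adverse_flag`.
#' @examples
#' coh <- load_cohort()
#' nrow(coh)  # 27
#' @export
load_cohort <- function(path = system.file("extdata", "cohort_tle_lev.tsv",
                                           package = "microvolt")) {
  if (!nzchar(path) || !file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("cohort file is empty")
  required <- c("id", "sex", "age", "seizure_frequency", "semiology",
                "aetiology", "eeg_focus", "outcome", "lev_dose_mg",
                "adverse_events")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("cohort file lacks column(s): ", paste(missing, collapse = ", "))
  }
  ok_outcome <- c("SF", "NSF>50", "NSF<50")
  bad <- setdiff(unique(df$outcome), ok_outcome)
  if (length(bad) > 0L) {
    stop("unknown outcome code(s): ", paste(bad, collapse = ", "))
  }
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  df$age <- as.numeric(df$age)
  df$lev_dose_mg <- as.numeric(df$lev_dose_mg)
  df$outcome <- factor(df$outcome, levels = ok_outcome)
  df$side <- ifelse(grepl("^Right", df$eeg_focus), "r-TLE", "l-TLE")
  df$structural <- !grepl("^Unknown", df$aetiology)
  df$adverse_flag <- df$adverse_events != "No"
  class(df) <- c("cohort_table", "data.frame")
  df
}

.round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize a cohort
#'
#' Counts and percentages for sex, focus side, outcome, structural aetiology
#' and adverse events, plus mean and sample (n-1) standard deviation of age
#' and levetiracetam dose. Percentages are 100 * count / n rounded half-up to
#' one decimal; means and SDs are reported unrounded with printed values at
#' one decimal.
#'
#' @param cohort A `cohort_table` from [load_cohort].
#' @return A list of class `cohort_summary` with components `n`, `counts`
#'   (data.frame: variable, level, count, percent) and `numeric`
#'   (data.frame: variable, mean, sd; `sd` is `NA` when n < 2).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(nrow(cohort) >= 1L)
  n <- nrow(cohort)
  one <- function(var, x) {
    tb <- table(x)
    data.frame(variable = var, level = names(tb),
               count = as.integer(tb),
               percent = .round_half_up(100 * as.integer(tb) / n),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  counts <- rbind(
    one("sex", cohort$sex),
    one("side", cohort$side),
    one("outcome", cohort$outcome),
    one("structural", ifelse(cohort$structural, "structural", "non-structural")),
    one("adverse_events", ifelse(cohort$adverse_flag, "yes", "no")))
  sd_or_na <- function(x) if (length(x) >= 2L) stats::sd(x) else NA_real_
  num <- data.frame(
    variable = c("age", "lev_dose_mg"),
    mean = c(mean(cohort$age), mean(cohort$lev_dose_mg)),
    sd = c(sd_or_na(cohort$age), sd_or_na(cohort$lev_dose_mg)),
    stringsAsFactors = FALSE)
  structure(list(n = n, counts = counts, numeric = num),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (n = ", x$n, ")\n", sep = "")
  for (i in seq_len(nrow(x$counts))) {
    with(x$counts[i, ], cat(sprintf("  %-15s %-15s %2d (%.1f%%)\n",
                                    variable, level, count, percent)))
  }
  for (i in seq_len(nrow(x$numeric))) {
    with(x$numeric[i, ], cat(sprintf("  %-15s mean %.1f, sd %.2f\n",
                                     variable, mean, sd)))
  }
  invisible(x)
}
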