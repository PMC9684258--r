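#' Electrode montages
#'
#' A montage is an ordered set of electrode labels together with 2-D scalp
#' positions obtained by azimuthal projection onto the unit disc (nose up,
#' right ear at positive x). The ordering is authoritative: every
#' channels-by-samples matrix in the package uses montage order for its rows.
#'
#' @param names Character vector of unique electrode labels.
#' @param positions Numeric matrix with one row per electrode and columns
#'   `x`, `y`; all positions must lie within the unit disc.
#' @return An object of class `eeg_montage` with elements `names` and
#'   `positions`.
#' @examples
#' m <- standard_montage()
#' length(m$names)  # 19
#' @export
eeg_montage <- function(names, positions) {
  names <- as.character(names)
  if (anyDuplicated(names) > 0L) {
    stop("montage labels must be unique")
  }
  positions <- as.matrix(positions)
  if (nrow(positions) != length(names) || ncol(positions) != 2L) {
    stop("'positions' must be a length(names) x 2 matrix")
  }
  if (any(!is.finite(positions))) stop("montage positions must be finite")
  if (any(sqrt(rowSums(positions^2)) > 1 + 1e-9)) {
    stop("montage positions must lie within the unit disc")
  }
  dimnames(positions) <- list(names, c("x", "y"))
  structure(list(names = names, positions = positions),
            class = "eeg_montage")
}

# Projected 10/20 coordinates: outer-ring electrodes on a circle of radius
# 0.9, mid-line and parasagittal electrodes at conventional schematic spots.
.standard_1020_19 <- function() {
  outer <- function(deg) 0.9 * c(cos(deg * pi / 180), sin(deg * pi / 180))
  pos <- rbind(
    Fp1 = outer(108), Fp2 = outer(72),
    F7  = outer(144), F3 = c(-0.34, 0.41), Fz = c(0, 0.45),
    F4  = c(0.34, 0.41), F8 = outer(36),
    T3  = outer(180), C3 = c(-0.45, 0), Cz = c(0, 0),
    C4  = c(0.45, 0), T4 = outer(0),
    T5  = outer(216), P3 = c(-0.34, -0.41), Pz = c(0, -0.45),
    P4  = c(0.34, -0.41), T6 = outer(-36),
    O1  = outer(-108), O2 = outer(-72))
  eeg_montage(rownames(pos), pos)
}

#' Built-in montages
#'
#' `"standard-1020-19"` is the nineteen-electrode international 10/20 set
#' (Fp1, Fp2, F7, F3, Fz, F4, F8, T3, C3, Cz, C4, T4, T5, P3, Pz, P4, T6,
#' O1, O2) used for conventional low-density clinical EEG.
#'
#' @param name Montage name; only `"standard-1020-19"` is built in.
#' @return An [eeg_montage] object.
#' @export
standard_montage <- function(name = "standard-1020-19") {
  switch(name,
         "standard-1020-19" = .standard_1020_19(),
         stop("unknown montage: ", name))
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$names), " electrodes: ",
      paste(x$names, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
length.eeg_montage <- function(x) length(x$names)
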