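# Profile/centroid spectrum container.

#' Mass spectrum container
#'
#' @param mz Strictly increasing m/z axis (Th).
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param label Free-text label.
#' @param charge Optional charge hint (NA if unknown).
#' @param centroided Logical flag; FALSE for profile data.
#' @return A `mass_spectrum` object.
#' @export
mass_spectrum <- function(mz, intensity, label = "", charge = NA_integer_,
                          centroided = FALSE) {
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length", call. = FALSE)
  }
  if (length(mz) == 0) stop("empty spectrum", call. = FALSE)
  if (any(diff(mz) <= 0)) stop("m/z axis must be strictly increasing",
                               call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be non-negative",
                               call. = FALSE)
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 label = label, charge = charge, centroided = centroided),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass spectrum> %s: %d points, m/z %.4f-%.4f%s\n",
              if (nzchar(x$label)) x$label else "(unlabeled)",
              length(x$mz), min(x$mz), max(x$mz),
              if (!is.na(x$charge)) paste0(", charge ", x$charge, "+") else ""))
  invisible(x)
}

#' Estimate charge from isotopologue spacing
#'
#' Picks local maxima above a relative intensity threshold and returns the
#' nearest integer to the reciprocal of the median spacing between adjacent
#' peaks — the standard isotope-spacing charge readout for resolved envelopes.
#'
#' @param spec A `mass_spectrum` containing one isotopically resolved envelope.
#' @param min_rel Peaks below `min_rel * max(intensity)` are ignored.
#' @return Integer charge estimate.
#' @export
estimate_charge <- function(spec, min_rel = 0.05) {
  stopifnot(inherits(spec, "mass_spectrum"))
  y <- spec$intensity
  if (all(y == 0)) stop("spectrum has no signal", call. = FALSE)
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE) & y > min_rel * max(y)
  peaks <- spec$mz[is_max]
  if (length(peaks) < 2) stop("need at least two resolved peaks", call. = FALSE)
  spacing <- stats::median(diff(peaks))
  as.integer(round(1 / spacing))
}
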