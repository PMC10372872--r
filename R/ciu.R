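# Collision-induced unfolding fingerprints (CE x CCS intensity maps) and
# conformer population ratios.

#' Build a CIU fingerprint
#'
#' Transforms per-collision-energy arrival-time distributions of one
#' quadrupole-selected ion to CCS space, resamples them onto a common CCS
#' grid, and normalizes each CE column to unit maximum (the standard CIU
#' fingerprint convention; `normalize = "area"` switches to unit-area
#' columns).
#'
#' @param atds Named list mapping collision energy (V, names coercible to
#'   numeric) to `atd` objects of the same ion (>= 2 energies).
#' @param cal A `ccs_calibration`.
#' @param ccs_grid Optional common CCS grid; default 512 points spanning all
#'   transformed distributions.
#' @param normalize `"max"` (default) or `"area"`.
#' @return A `ciu_fingerprint`: `ce_axis` (ascending), `ccs_axis`, `matrix`
#'   (rows = CCS, columns = CE).
#' @export
build_fingerprint <- function(atds, cal, ccs_grid = NULL,
                              normalize = c("max", "area")) {
  normalize <- match.arg(normalize)
  if (length(atds) < 2) stop("need ATDs for at least 2 collision energies",
                             call. = FALSE)
  ce <- as.numeric(names(atds))
  if (any(is.na(ce))) stop("ATD list names must be collision energies (V)",
                           call. = FALSE)
  ids <- unique(vapply(atds, function(a) paste(a$label, a$mass, a$charge),
                       character(1)))
  if (length(ids) != 1) {
    stop("inconsistent ion identity across collision energies", call. = FALSE)
  }
  o <- order(ce)
  ce <- ce[o]
  dists <- lapply(atds[o], atd_to_ccs, cal = cal)
  if (is.null(ccs_grid)) {
    rng <- range(unlist(lapply(dists, function(d) range(d$ccs))))
    ccs_grid <- seq(rng[1], rng[2], length.out = 512)
  }
  mat <- vapply(dists, function(d) {
    y <- stats::approx(d$ccs, d$intensity, xout = ccs_grid,
                       yleft = 0, yright = 0)$y
    if (normalize == "max") {
      if (max(y) > 0) y / max(y) else y
    } else {
      a <- pracma::trapz(ccs_grid, y)
      if (a > 0) y / a else y
    }
  }, numeric(length(ccs_grid)))
  structure(list(ce_axis = ce, ccs_axis = ccs_grid,
                 matrix = matrix(mat, nrow = length(ccs_grid),
                                 dimnames = list(NULL, ce)),
                 ion = dists[[1]]$ion),
            class = "ciu_fingerprint")
}

#' @export
print.ciu_fingerprint <- function(x, ...) {
  cat(sprintf("<CIU fingerprint> %s%d+: %d CE steps (%.0f-%.0f V) x %d CCS bins\n",
              if (nzchar(x$ion$label)) paste0(x$ion$label, " ") else "",
              x$ion$charge, length(x$ce_axis), min(x$ce_axis), max(x$ce_axis),
              length(x$ccs_axis)))
  invisible(x)
}

#' Compact/extended conformer fractions
#'
#' Integrates (trapezoid rule) the intensity below and above a CCS boundary
#' and normalizes the two areas to sum to 1. The boundary point is split by
#' linear interpolation so the fractions vary continuously with the boundary.
#'
#' @param dist A `ccs_distribution`, or any list with `ccs` and `intensity`.
#' @param boundary CCS boundary (A^2) separating compact from extended; must
#'   lie within the grid range.
#' @return Named numeric vector `c(compact = , extended = )` summing to 1.
#' @export
conformer_ratio <- function(dist, boundary) {
  ccs <- dist$ccs
  y <- dist$intensity
  if (boundary < min(ccs) || boundary > max(ccs)) {
    stop("boundary must lie within the CCS grid", call. = FALSE)
  }
  total <- pracma::trapz(ccs, y)
  if (total <= 0) stop("zero total intensity", call. = FALSE)
  yb <- stats::approx(ccs, y, xout = boundary)$y
  below <- ccs <= boundary
  x_lo <- c(ccs[below], boundary)
  y_lo <- c(y[below], yb)
  compact <- pracma::trapz(x_lo, y_lo) / total
  c(compact = compact, extended = 1 - compact)
}

#' Extended-conformer fraction per CIU column
#'
#' @param fp A `ciu_fingerprint`.
#' @param boundary CCS boundary (A^2); default from [find_boundary()].
#' @return Named numeric vector of extended fractions, one per CE.
#' @export
extended_fraction <- function(fp, boundary = find_boundary(fp)) {
  stopifnot(inherits(fp, "ciu_fingerprint"))
  vapply(seq_along(fp$ce_axis), function(j) {
    conformer_ratio(list(ccs = fp$ccs_axis, intensity = fp$matrix[, j]),
                    boundary)[["extended"]]
  }, numeric(1)) |> stats::setNames(fp$ce_axis)
}

#' Default compact/extended boundary
#'
#' Sums the fingerprint over CE, locates the two largest modes of the summed
#' distribution, and returns the CCS of the intensity minimum between them.
#'
#' @param fp A `ciu_fingerprint`.
#' @return Boundary CCS (A^2).
#' @export
find_boundary <- function(fp) {
  stopifnot(inherits(fp, "ciu_fingerprint"))
  y <- .smooth_gauss(rowSums(fp$matrix), 2)
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  peaks <- which(is_max)
  if (length(peaks) < 2) {
    stop("fewer than two modes in the summed distribution; supply a boundary",
         call. = FALSE)
  }
  top2 <- sort(peaks[order(-y[peaks])][1:2])
  seg <- top2[1]:top2[2]
  fp$ccs_axis[seg[which.min(y[seg])]]
}

#' First CE at which the extended conformer dominates
#'
#' @param fp A `ciu_fingerprint`.
#' @param boundary CCS boundary (A^2).
#' @return The lowest CE (V) whose extended fraction exceeds 0.5 (NA if
#'   never).
#' @export
transition_ce <- function(fp, boundary = find_boundary(fp)) {
  ef <- extended_fraction(fp, boundary)
  hit <- which(ef > 0.5)
  if (length(hit) == 0) return(NA_real_)
  fp$ce_axis[hit[1]]
}
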