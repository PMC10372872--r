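# Traveling-wave ion-mobility calibration and CCS distributions.
#
# Standard TW protocol: corrected drift time t' = t - edc*sqrt(m/z)/1000,
# reduced-mass/charge-corrected reference CCS' = CCS_ref * sqrt(mu) / z, and
# a power law CCS' = A * t'^B fitted as a line in ln-ln space.

#' Bundled TW calibrant reference table
#'
#' Native-mode nitrogen CCS reference values for ubiquitin, cytochrome c and
#' beta-lactoglobulin, keyed by (protein, charge). Nominal literature values
#' (Bush laboratory compilation); see the packaged CSV header for the version
#' stamp. Measured arrival times must be supplied per experiment.
#'
#' @return data.frame with columns `name`, `charge`, `mass`, `ccs_ref`.
#' @export
tw_calibrants <- function() {
  path <- system.file("extdata", "tw_calibrants_n2.csv", package = "metims")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Build a calibrant entry table
#'
#' @param name,charge,mass,ccs_ref,t_arrival Vectors of equal length: label,
#'   charge state, neutral mass (Da), reference CCS (A^2, nitrogen), and the
#'   measured arrival time (ms).
#' @return data.frame of calibrant entries.
#' @export
calibrant_entries <- function(name, charge, mass, ccs_ref, t_arrival) {
  df <- data.frame(name = name, charge = as.integer(charge),
                   mass = as.numeric(mass), ccs_ref = as.numeric(ccs_ref),
                   t_arrival = as.numeric(t_arrival),
                   stringsAsFactors = FALSE)
  if (any(df$charge <= 0 | df$mass <= 0 | df$ccs_ref <= 0 | df$t_arrival <= 0)) {
    stop("calibrant charges, masses, CCS and times must all be positive",
         call. = FALSE)
  }
  df
}

.reduced_mass <- function(ion_mass, gas_mass) {
  ion_mass * gas_mass / (ion_mass + gas_mass)
}

#' Calibrate the traveling-wave mobility axis
#'
#' Fits `ln(CCS') = ln(A) + B * ln(t')` by least squares over the calibrant
#' entries, where `t' = t - edc * sqrt(m/z) / 1000` (EDC delay correction,
#' `t` in ms) and `CCS' = CCS_ref * sqrt(mu) / z` with reduced mass
#' `mu = m * m_gas / (m + m_gas)`.
#'
#' @param entries Calibrant table from [calibrant_entries()] (>= 3 rows whose
#'   corrected times span more than a tenth of a decade).
#' @param edc EDC delay coefficient (instrument constant; required, no
#'   default).
#' @param gas_mass Drift gas mass in Da (default nitrogen, 28.0134).
#' @param tw_set Optional label for the TW velocity/height parameter set;
#'   calibrations are never mixed across sets.
#' @return A `ccs_calibration` with fields `A`, `B`, `edc`, `gas_mass`,
#'   `r_squared`, `residuals` (per-entry relative CCS residuals), `tw_set`.
#' @export
calibrate_tw <- function(entries, edc, gas_mass = 28.0134, tw_set = NULL) {
  if (!is.data.frame(entries) || nrow(entries) < 3) {
    stop("need at least 3 calibrant entries", call. = FALSE)
  }
  if (missing(edc)) stop("edc coefficient is required (no silent default)",
                         call. = FALSE)
  mz <- (entries$mass + entries$charge * PROTON_MASS) / entries$charge
  tprime <- entries$t_arrival - edc * sqrt(mz) / 1000
  if (any(tprime <= 0)) {
    bad <- entries$name[which(tprime <= 0)[1]]
    stop("non-positive corrected drift time for calibrant: ", bad,
         call. = FALSE)
  }
  if (diff(range(log10(tprime))) <= 0.1) {
    stop("degenerate calibration: corrected times span too small a range",
         call. = FALSE)
  }
  mu <- .reduced_mass(entries$mass, gas_mass)
  ccs_prime <- entries$ccs_ref * sqrt(mu) / entries$charge
  fit <- stats::lm(log(ccs_prime) ~ log(tprime))
  A <- exp(stats::coef(fit)[[1]])
  B <- stats::coef(fit)[[2]]
  pred <- A * tprime^B * entries$charge / sqrt(mu)
  res <- (pred - entries$ccs_ref) / entries$ccs_ref
  lhs <- log(ccs_prime)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((lhs - mean(lhs))^2)
  structure(list(A = A, B = B, edc = edc, gas_mass = gas_mass,
                 r_squared = r2, residuals = res, tw_set = tw_set,
                 entries = entries),
            class = "ccs_calibration")
}

#' @export
print.ccs_calibration <- function(x, ...) {
  cat(sprintf("<TW CCS calibration> A = %.4f, B = %.4f, R^2 = %.6f%s\n",
              x$A, x$B, x$r_squared,
              if (!is.null(x$tw_set)) paste0(" [", x$tw_set, "]") else ""))
  invisible(x)
}

#' Arrival-time distribution container
#'
#' @param time Ascending drift-time grid (ms).
#' @param intensity Non-negative intensities.
#' @param mass,charge Neutral mass (Da) and charge of the selected ion.
#' @param label Species label.
#' @param tw_set Optional TW parameter-set tag (must match the calibration's).
#' @return An `atd` object. The ion m/z is derived from mass and charge.
#' @export
atd <- function(time, intensity, mass, charge, label = "", tw_set = NULL) {
  if (length(time) != length(intensity)) {
    stop("time and intensity must have equal length", call. = FALSE)
  }
  if (any(diff(time) <= 0)) stop("time grid must be ascending", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  structure(list(time = as.numeric(time), intensity = as.numeric(intensity),
                 mass = mass, charge = as.integer(charge),
                 mz = (mass + charge * PROTON_MASS) / charge,
                 label = label, tw_set = tw_set),
            class = "atd")
}

#' Transform an arrival-time distribution to a CCS distribution
#'
#' Maps each time through `CCS = A * t'^B * z / sqrt(mu)`; intensities are
#' carried over unchanged (no Jacobian correction — the common convention for
#' apex/FWHM reporting). Times yielding non-positive corrected time are
#' dropped with a warning.
#'
#' @param x An `atd`.
#' @param cal A `ccs_calibration` (same `tw_set` as the ATD, if both tagged).
#' @param smooth_sigma Smoothing width in grid steps for the apex/FWHM
#'   summary (see [summarize_ccs()]).
#' @return A `ccs_distribution` with fields `ccs`, `intensity`, `apex`,
#'   `fwhm`, `ion`.
#' @export
atd_to_ccs <- function(x, cal, smooth_sigma = 2) {
  stopifnot(inherits(x, "atd"), inherits(cal, "ccs_calibration"))
  if (!is.null(x$tw_set) && !is.null(cal$tw_set) &&
      !identical(x$tw_set, cal$tw_set)) {
    stop(sprintf("TW parameter set mismatch: ATD '%s' vs calibration '%s'",
                 x$tw_set, cal$tw_set), call. = FALSE)
  }
  tprime <- x$time - cal$edc * sqrt(x$mz) / 1000
  drop <- tprime <= 0
  if (any(drop)) {
    warning(sprintf("dropped %d points with non-positive corrected time",
                    sum(drop)))
  }
  tprime <- tprime[!drop]
  inten <- x$intensity[!drop]
  if (length(tprime) == 0) stop("no usable points after EDC correction",
                                call. = FALSE)
  mu <- .reduced_mass(x$mass, cal$gas_mass)
  ccs <- cal$A * tprime^cal$B * x$charge / sqrt(mu)
  out <- structure(list(ccs = ccs, intensity = inten,
                        ion = list(label = x$label, mass = x$mass,
                                   charge = x$charge, mz = x$mz)),
                   class = "ccs_distribution")
  s <- summarize_ccs(out, smooth_sigma = smooth_sigma)
  out$apex <- s[["apex"]]
  out$fwhm <- s[["fwhm"]]
  out
}

#' @export
print.ccs_distribution <- function(x, ...) {
  cat(sprintf("<CCS distribution> %s%d+: apex %.1f A^2, FWHM %.1f A^2\n",
              if (nzchar(x$ion$label)) paste0(x$ion$label, " ") else "",
              x$ion$charge, x$apex, x$fwhm))
  invisible(x)
}

# Gaussian smoothing on the index axis with sd = sigma grid steps
.smooth_gauss <- function(y, sigma) {
  if (sigma <= 0 || length(y) < 3) return(y)
  half <- ceiling(4 * sigma)
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  n <- length(y)
  ypad <- c(rep(y[1], half), y, rep(y[n], half))
  as.numeric(stats::filter(ypad, k, sides = 2))[(half + 1):(half + n)]
}

#' Invert a TW calibration: arrival time for a target CCS
#'
#' Maps a CCS value back to the drift time at which a calibrated ion of the
#' given mass and charge would arrive (including the EDC delay). Used to
#' place synthetic conformers on the time axis.
#'
#' @param ccs CCS in A^2 (vectorized).
#' @param cal A `ccs_calibration`.
#' @param mass,charge Ion neutral mass (Da) and charge.
#' @return Arrival time(s) in ms.
#' @export
ccs_to_time <- function(ccs, cal, mass, charge) {
  stopifnot(inherits(cal, "ccs_calibration"))
  mu <- .reduced_mass(mass, cal$gas_mass)
  mz <- (mass + charge * PROTON_MASS) / charge
  tprime <- (ccs * sqrt(mu) / (charge * cal$A))^(1 / cal$B)
  tprime + cal$edc * sqrt(mz) / 1000
}

#' Apex and FWHM of a CCS distribution
#'
#' Apex is the grid point of maximum intensity after optional Gaussian
#' smoothing (sd expressed in grid steps; ties broken toward the lowest CCS).
#' FWHM is obtained by linear interpolation at half maximum on both flanks of
#' the apex mode; a delta-like single-bin mode reports one grid step by
#' convention. Both summaries are exactly invariant to uniform intensity
#' scaling.
#'
#' @param ccsd A `ccs_distribution` (or any list with `ccs` and `intensity`).
#' @param smooth_sigma Smoothing sd in grid steps (default 2; 0 disables).
#' @return Named numeric vector `c(apex = , fwhm = )` in A^2.
#' @export
summarize_ccs <- function(ccsd, smooth_sigma = 2) {
  ccs <- ccsd$ccs
  y <- ccsd$intensity
  if (length(ccs) == 0 || all(y == 0)) {
    stop("cannot summarize an all-zero CCS distribution", call. = FALSE)
  }
  ys <- .smooth_gauss(y, smooth_sigma)
  imax <- which.max(ys)  # which.max returns the first (lowest-CCS) maximum
  apex <- ccs[imax]
  half <- ys[imax] / 2
  step <- if (length(ccs) > 1) stats::median(diff(ccs)) else 1
  # walk down both flanks of the apex mode to the half-max crossings
  left <- imax
  while (left > 1 && ys[left - 1] <= ys[left] && ys[left - 1] > half) {
    left <- left - 1
  }
  right <- imax
  n <- length(ys)
  while (right < n && ys[right + 1] <= ys[right] && ys[right + 1] > half) {
    right <- right + 1
  }
  x_left <- if (left > 1 && ys[left - 1] <= half) {
    stats::approx(ys[c(left - 1, left)], ccs[c(left - 1, left)], xout = half)$y
  } else NA_real_
  x_right <- if (right < n && ys[right + 1] <= half) {
    stats::approx(ys[c(right + 1, right)], ccs[c(right + 1, right)],
                  xout = half)$y
  } else NA_real_
  fwhm <- if (!is.na(x_left) && !is.na(x_right)) x_right - x_left else step
  c(apex = apex, fwhm = max(fwhm, step))
}
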