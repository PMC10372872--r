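# Synthetic-data generators emulating the experimental observables: charge-
# state isotope envelopes of overlapping Cu/Zn/disulfide species, multi-
# conformer arrival-time distributions drifting with collision energy,
# sigmoidal survival-yield curves, and fragment peak lists with decoys.
# Every generator is a pure function of (parameters, seed); a seed is
# mandatory whenever noise is requested.

#' Simulate a native mass spectrum of a species mixture
#'
#' Renders the isotopic profile of each species at each charge, weights
#' species by their fractional abundances (areas in the noise-free spectrum
#' are proportional to the fractions), sums onto a common m/z grid, and
#' optionally adds Gaussian intensity noise.
#'
#' @param species List of `metal_complex` objects.
#' @param fractions Fractional abundances, summing to 1 (default equal).
#' @param charges Integer charge states to include (default 5, the charge
#'   state examined throughout the bundled analyses).
#' @param charge_weights Relative weight per charge state (default equal).
#' @param resolving_power FWHM resolving power (default 20000).
#' @param grid_step m/z grid step (default FWHM/10 at the lowest m/z).
#' @param noise_sd Gaussian noise sd relative to the maximum intensity
#'   (default 0 = noise-free; 0.01 is the study's standard noisy condition).
#' @param seed Integer seed; mandatory when `noise_sd > 0`.
#' @param prune,bin_width Passed to [isotope_pattern()].
#' @return A `mass_spectrum`; the generating truth is attached as attribute
#'   `"truth"`.
#' @export
synth_spectrum <- function(species, fractions = NULL, charges = 5,
                           charge_weights = NULL, resolving_power = 20000,
                           grid_step = NULL, noise_sd = 0, seed = NULL,
                           prune = 1e-10, bin_width = 1e-4) {
  if (length(species) == 0) stop("empty species list", call. = FALSE)
  if (inherits(species, "metal_complex")) species <- list(species)
  if (is.null(fractions)) fractions <- rep(1 / length(species), length(species))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  if (is.null(charge_weights)) {
    charge_weights <- rep(1 / length(charges), length(charges))
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is mandatory for noisy output", call. = FALSE)
  }
  pats <- lapply(species, function(sp) {
    .cached_pattern(species_composition(sp), prune, bin_width)
  })
  rel_sigma <- 1 / (resolving_power * 2 * sqrt(2 * log(2)))
  mz_pats <- list()
  w <- numeric(0)
  for (i in seq_along(pats)) {
    for (j in seq_along(charges)) {
      mz_pats[[length(mz_pats) + 1L]] <- to_mz(pats[[i]], charges[j])
      w <- c(w, fractions[i] * charge_weights[j])
    }
  }
  rng <- range(unlist(lapply(mz_pats, function(p) range(p$mass))))
  fwhm_min <- rng[1] / resolving_power
  if (is.null(grid_step)) grid_step <- fwhm_min / 10
  grid <- seq(rng[1] - 10 * fwhm_min, rng[2] + 10 * fwhm_min, by = grid_step)
  y <- numeric(length(grid))
  for (i in seq_along(mz_pats)) {
    y <- y + w[i] * .render_on_grid(mz_pats[[i]]$mass, mz_pats[[i]]$abundance,
                                    rel_sigma, grid)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), sd = noise_sd * max(y))
    y[y < 0] <- 0
  }
  out <- mass_spectrum(grid, y, label = "synthetic",
                       charge = if (length(charges) == 1) charges else NA_integer_)
  attr(out, "truth") <- list(
    species = vapply(species, function(sp) sp$label, character(1)),
    n_cu = vapply(species, function(sp) sp$n_cu, integer(1)),
    n_zn = vapply(species, function(sp) sp$n_zn, integer(1)),
    n_ss = vapply(species, function(sp) sp$n_ss, integer(1)),
    fractions = fractions, charges = charges, noise_sd = noise_sd,
    seed = seed)
  out
}

#' Simulate a collision-induced unfolding series
#'
#' Generates one arrival-time distribution per collision energy as a
#' two-Gaussian mixture in drift-time space whose components correspond
#' (through the inverse TW calibration) to a compact and an extended
#' conformer; the extended fraction follows a logistic transition in CE with
#' the programmed midpoint. Defaults mirror the study conditions for the
#' Zn7-loaded protein 5+ ion: compact ~1000 A^2, extended ~1300 A^2, trap CE
#' ramp 0-60 V.
#'
#' @param cal A `ccs_calibration` used to place the conformers in time.
#' @param mass,charge Ion neutral mass (Da) and charge.
#' @param midpoint_ce Logistic transition midpoint (V).
#' @param logistic_width Logistic width (V; default 3).
#' @param compact_ccs,extended_ccs Conformer CCS centers (A^2); compact must
#'   be smaller.
#' @param ccs_widths Gaussian sd of each conformer in CCS space (A^2).
#' @param ce_grid Collision energies (V; default 0-60 in 5 V steps).
#' @param time_grid Drift-time grid (ms; default 0-14 ms, 300 points).
#' @param noise_sd Relative Gaussian noise (default 0).
#' @param seed Seed, mandatory when `noise_sd > 0`.
#' @param label Ion label carried on every ATD.
#' @return Named list (CE as names) of `atd` objects.
#' @export
synth_ciu <- function(cal, mass, charge, midpoint_ce = 30, logistic_width = 3,
                      compact_ccs = 1000, extended_ccs = 1300,
                      ccs_widths = c(25, 35), ce_grid = seq(0, 60, by = 5),
                      time_grid = NULL,
                      noise_sd = 0, seed = NULL, label = "ion") {
  if (compact_ccs >= extended_ccs) {
    stop("compact_ccs must be smaller than extended_ccs", call. = FALSE)
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is mandatory for noisy output", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  centers_t <- ccs_to_time(c(compact_ccs, extended_ccs), cal, mass, charge)
  # convert CCS-space widths to time-space via the local derivative dt/dccs
  widths_t <- abs(ccs_to_time(c(compact_ccs, extended_ccs) + 1, cal, mass,
                               charge) - centers_t) * ccs_widths
  if (is.null(time_grid)) {
    lo <- max(centers_t[1] - 6 * widths_t[1], 1e-3)
    hi <- centers_t[2] + 6 * widths_t[2]
    time_grid <- seq(lo, hi, length.out = 400)
  }
  out <- lapply(ce_grid, function(ce) {
    f_ext <- stats::plogis((ce - midpoint_ce) / logistic_width)
    y <- (1 - f_ext) * stats::dnorm(time_grid, centers_t[1], widths_t[1]) +
      f_ext * stats::dnorm(time_grid, centers_t[2], widths_t[2])
    if (noise_sd > 0) {
      y <- y + stats::rnorm(length(y), sd = noise_sd * max(y))
      y[y < 0] <- 0
    }
    atd(time_grid, y, mass = mass, charge = charge, label = label,
        tw_set = cal$tw_set)
  })
  names(out) <- ce_grid
  out
}

#' Simulate a survival-yield curve
#'
#' Samples the sigmoid `bottom + (top - bottom) / (1 + exp((E - e50)/w))` on
#' an energy grid and adds Gaussian noise clipped to \[0, 1\].
#'
#' @param e50 Midpoint (eV).
#' @param w Sigmoid width (eV, > 0).
#' @param e_grid Center-of-mass energies (eV).
#' @param noise_sd Gaussian noise sd on SY (default 0).
#' @param seed Seed, mandatory when `noise_sd > 0`.
#' @param top,bottom Asymptotes (defaults 1 and 0).
#' @param ion Label.
#' @return A `sy_curve`.
#' @export
synth_sy <- function(e50, w, e_grid = seq(0.5, 1.5, length.out = 15),
                     noise_sd = 0, seed = NULL, top = 1, bottom = 0,
                     ion = "ion") {
  if (w <= 0) stop("w must be positive", call. = FALSE)
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is mandatory for noisy output", call. = FALSE)
  }
  sy <- bottom + (top - bottom) / (1 + exp((e_grid - e50) / w))
  if (noise_sd > 0) {
    set.seed(seed)
    sy <- sy + stats::rnorm(length(sy), sd = noise_sd)
  }
  sy <- pmin(pmax(sy, 0), 1)
  sy_curve(e_grid, sy, ion = ion)
}

#' Simulate a top-down peak list with planted fragments and decoys
#'
#' Plants peaks at the theoretical m/z of the supplied fragments (with
#' optional ppm jitter) and adds decoy peaks guaranteed to lie at least
#' `decoy_min_ppm` from every theoretical fragment m/z (rejection sampling;
#' errors out if a decoy cannot be placed).
#'
#' @param fragments `fragment_ions` rows to plant.
#' @param all_theoretical Full theoretical fragment table used for the decoy
#'   exclusion zones (default: `fragments` itself).
#' @param ppm_jitter Sd of the Gaussian ppm jitter on planted peaks
#'   (default 0 = exact).
#' @param n_decoys Number of decoy peaks (default 100).
#' @param decoy_min_ppm Minimum distance of any decoy from any theoretical
#'   m/z, in ppm (default 50).
#' @param mz_range Range for decoy placement (default the fragment m/z range
#'   widened by 10%).
#' @param seed Integer seed (mandatory: decoy placement is stochastic).
#' @param max_tries Rejection-sampling budget per decoy.
#' @return data.frame with columns `mz`, `intensity`, `is_decoy`.
#' @export
synth_fragment_peaks <- function(fragments, all_theoretical = fragments,
                                 ppm_jitter = 0, n_decoys = 100,
                                 decoy_min_ppm = 50, mz_range = NULL,
                                 seed, max_tries = 1000) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  set.seed(seed)
  theo <- sort(all_theoretical$mz)
  if (is.null(mz_range)) {
    mz_range <- range(fragments$mz) * c(0.95, 1.05)
  }
  mz <- fragments$mz
  if (ppm_jitter > 0) {
    mz <- mz * (1 + stats::rnorm(length(mz), sd = ppm_jitter) * 1e-6)
  }
  planted <- data.frame(mz = mz,
                        intensity = stats::runif(length(mz), 0.2, 1),
                        is_decoy = FALSE)
  decoys <- numeric(n_decoys)
  for (i in seq_len(n_decoys)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, mz_range[1], mz_range[2])
      # distance to nearest theoretical m/z in ppm of that m/z
      j <- findInterval(x, theo)
      near <- theo[pmax(pmin(c(j, j + 1), length(theo)), 1)]
      if (all(abs(x - near) / near * 1e6 >= decoy_min_ppm)) {
        decoys[i] <- x
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place a decoy outside the exclusion zones", call. = FALSE)
    }
  }
  out <- rbind(planted,
               data.frame(mz = decoys,
                          intensity = stats::runif(n_decoys, 0.05, 0.5),
                          is_decoy = TRUE))
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}
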