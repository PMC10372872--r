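# Metal/disulfide stoichiometry assignment: enumerate candidate species, fit
# their theoretical isotopic envelopes to observed spectra, score, and rank.

#' Candidate grid for stoichiometry assignment
#'
#' Defines the (n_cu, n_zn, n_ss) search space. The default ranges cover the
#' species ladder seen when Zn7-loaded metallothionein-3 reacts with Cu(II):
#' up to 8 Cu(I), up to 7 Zn(II), and 0-2 intramolecular disulfides. Species
#' violating the thiol budgets of [metal_complex()] are dropped during
#' enumeration, as are species outside the optional mass window.
#'
#' @param cu,zn,ss Integer vectors of admissible counts.
#' @param check_budget Apply the cysteine-derived budgets (default TRUE).
#' @param mass_target,mass_window Optional: keep only species whose average
#'   mass lies within `mass_target +/- mass_window` Da.
#' @return A `candidate_grid` object.
#' @export
candidate_grid <- function(cu = 0:8, zn = 0:7, ss = 0:2, check_budget = TRUE,
                           mass_target = NULL, mass_window = NULL) {
  if (length(cu) == 0 || length(zn) == 0 || length(ss) == 0) {
    stop("candidate ranges must be non-empty", call. = FALSE)
  }
  if (!is.null(mass_target) && is.null(mass_window)) {
    stop("mass_window required when mass_target is given", call. = FALSE)
  }
  structure(list(cu = sort(unique(as.integer(cu))),
                 zn = sort(unique(as.integer(zn))),
                 ss = sort(unique(as.integer(ss))),
                 check_budget = check_budget,
                 mass_target = mass_target, mass_window = mass_window),
            class = "candidate_grid")
}

#' Enumerate candidate species over a grid
#'
#' Returns every species in the Cartesian product of the grid ranges that
#' satisfies the [metal_complex()] budgets (when enabled) and the optional
#' mass window, in lexicographic (n_cu, n_zn, n_ss) order.
#'
#' @param grid A `candidate_grid`.
#' @param base A `protein_sequence`.
#' @return A list of `metal_complex` objects (possibly empty, with a warning).
#' @export
enumerate_candidates <- function(grid, base) {
  stopifnot(inherits(grid, "candidate_grid"), inherits(base, "protein_sequence"))
  combos <- expand.grid(ss = grid$ss, zn = grid$zn, cu = grid$cu,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[order(combos$cu, combos$zn, combos$ss), , drop = FALSE]
  out <- vector("list", nrow(combos))
  kept <- 0L
  for (i in seq_len(nrow(combos))) {
    sp <- tryCatch(
      metal_complex(base, n_cu = combos$cu[i], n_zn = combos$zn[i],
                    n_ss = combos$ss[i], check_budget = grid$check_budget),
      error = function(e) NULL)
    if (is.null(sp)) next
    if (!is.null(grid$mass_target)) {
      m <- average_mass(species_composition(sp))
      if (abs(m - grid$mass_target) > grid$mass_window) next
    }
    kept <- kept + 1L
    out[[kept]] <- sp
  }
  out <- out[seq_len(kept)]
  if (kept == 0L) warning("no candidate species satisfy the grid constraints")
  out
}

#' Score a theoretical envelope against an observed spectrum
#'
#' Renders the theoretical pattern as a profile on the observed m/z grid and
#' computes a similarity score after optimizing a bounded global m/z shift
#' (absorbing small calibration offsets) and a non-negative intensity scale.
#' The default score is the cosine similarity between the rendered profile and
#' the observed intensities, which is 1 iff the two are proportional and is
#' invariant to intensity scaling. `method = "chisq"` instead maps the
#' scale-optimized reduced chi-square `x` to `1 / (1 + x)`.
#'
#' @param theoretical An m/z-domain `isotope_pattern` at charge `z`.
#' @param observed A `mass_spectrum` covering the envelope.
#' @param z Charge state (must match the pattern's charge).
#' @param resolving_power FWHM resolving power used for rendering.
#' @param mz_shift_bound Maximum |global m/z shift| in Th (default 0.05,
#'   smaller than the 0.2 Th isotope spacing at 5+ so the optimizer cannot hop
#'   isotopologues). Use 0 to disable the shift search.
#' @param method `"cosine"` (default) or `"chisq"`.
#' @return A `fit_result` list: `score` in \[0, 1\], `scale`, `mz_shift`,
#'   `residual` (RMS of observed minus scaled theoretical).
#' @export
score_fit <- function(theoretical, observed, z, resolving_power = 20000,
                      mz_shift_bound = 0.05, method = c("cosine", "chisq")) {
  stopifnot(inherits(theoretical, "isotope_pattern"),
            inherits(observed, "mass_spectrum"))
  method <- match.arg(method)
  if (theoretical$domain != "m/z") {
    stop("theoretical pattern must be in the m/z domain", call. = FALSE)
  }
  if (theoretical$charge != z) {
    stop(sprintf("pattern charge (%d) does not match z = %d",
                 theoretical$charge, z), call. = FALSE)
  }
  if (all(observed$intensity == 0)) {
    stop("observed spectrum is empty (no envelope)", call. = FALSE)
  }
  fwhm <- max(theoretical$mass) / resolving_power
  lo <- min(theoretical$mass) - 5 * fwhm
  hi <- max(theoretical$mass) + 5 * fwhm
  if (hi < min(observed$mz) || lo > max(observed$mz)) {
    stop("no overlap between theoretical envelope and observed spectrum range",
         call. = FALSE)
  }
  # work on the observed grid restricted to the envelope window
  idx <- which(observed$mz >= lo - mz_shift_bound &
               observed$mz <= hi + mz_shift_bound)
  grid <- observed$mz[idx]
  obs <- observed$intensity[idx]
  rel_sigma <- 1 / (resolving_power * 2 * sqrt(2 * log(2)))
  cosine_at <- function(shift) {
    th <- .render_on_grid(theoretical$mass + shift, theoretical$abundance,
                          rel_sigma, grid)
    den <- sqrt(sum(th^2) * sum(obs^2))
    if (den == 0) return(list(score = 0, th = th))
    list(score = sum(th * obs) / den, th = th)
  }
  shift <- 0
  if (mz_shift_bound > 0) {
    opt <- stats::optimize(function(s) cosine_at(s)$score,
                           c(-mz_shift_bound, mz_shift_bound), maximum = TRUE)
    # keep zero shift unless the optimizer genuinely improves on it
    if (opt$objective > cosine_at(0)$score + 1e-12) shift <- opt$maximum
  }
  at <- cosine_at(shift)
  th <- at$th
  sc <- if (sum(th^2) > 0) max(sum(th * obs) / sum(th^2), 0) else 0
  resid <- sqrt(mean((obs - sc * th)^2))
  score <- at$score
  if (method == "chisq") {
    denom <- pmax(sc * th, max(obs) * 1e-3)
    chisq <- mean((obs - sc * th)^2 / denom)
    score <- 1 / (1 + chisq)
  }
  structure(list(species = NULL, charge = z, score = max(0, min(1, score)),
                 scale = sc, mz_shift = shift, residual = resid,
                 method = method),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit> %s z=%d score=%.4f shift=%+.4f Th residual=%.3g\n",
              if (is.null(x$species)) "?" else x$species$label,
              x$charge, x$score, x$mz_shift, x$residual))
  invisible(x)
}

#' Assign metal/disulfide stoichiometry to an observed envelope
#'
#' Fits the theoretical envelope of every candidate on the grid to the
#' observed spectrum and ranks candidates by descending score. Ties (within
#' `tie_tol`) are broken by parsimony: fewer total metals, then fewer
#' disulfides. Candidates whose envelope does not overlap the observed m/z
#' range score `NA` and rank last.
#'
#' @param observed A `mass_spectrum` containing one charge-state envelope.
#' @param grid A `candidate_grid`.
#' @param base A `protein_sequence`.
#' @param z Charge state of the envelope.
#' @param resolving_power,mz_shift_bound,method Passed to [score_fit()].
#' @param prune,bin_width Passed to [isotope_pattern()] (patterns are
#'   memoized per composition).
#' @param tie_tol Score difference treated as a tie (default 1e-9).
#' @return A data.frame of ranked results (one row per scored candidate) with
#'   columns `n_cu`, `n_zn`, `n_ss`, `score`, `scale`, `mz_shift`, `residual`,
#'   `label`; the score margin between the top two candidates is attached as
#'   attribute `"margin"`.
#' @export
assign_species <- function(observed, grid, base, z, resolving_power = 20000,
                           mz_shift_bound = 0.05, method = "cosine",
                           prune = 1e-10, bin_width = 1e-4, tie_tol = 1e-9) {
  candidates <- enumerate_candidates(grid, base)
  if (length(candidates) == 0) stop("empty candidate set", call. = FALSE)
  rows <- lapply(candidates, function(sp) {
    pat <- .cached_pattern(species_composition(sp), prune, bin_width)
    fit <- tryCatch(
      score_fit(to_mz(pat, z), observed, z, resolving_power = resolving_power,
                mz_shift_bound = mz_shift_bound, method = method),
      error = function(e) NULL)
    data.frame(n_cu = sp$n_cu, n_zn = sp$n_zn, n_ss = sp$n_ss,
               score = if (is.null(fit)) NA_real_ else fit$score,
               scale = if (is.null(fit)) NA_real_ else fit$scale,
               mz_shift = if (is.null(fit)) NA_real_ else fit$mz_shift,
               residual = if (is.null(fit)) NA_real_ else fit$residual,
               label = sp$label, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  # rank: descending score with parsimony tie-break (fewer metals, fewer SS);
  # quantize scores by tie_tol so near-exact ties resolve deterministically
  qscore <- round(res$score / tie_tol) * tie_tol
  ord <- order(-qscore, res$n_cu + res$n_zn, res$n_ss, na.last = TRUE)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  scores <- res$score[!is.na(res$score)]
  attr(res, "margin") <- if (length(scores) >= 2) scores[1] - scores[2] else NA
  res
}

#' Non-negative least-squares mixture fit
#'
#' Decomposes an observed envelope over a basis of candidate species profiles
#' rendered on the observed grid, by NNLS. Reported `fractions` are the
#' coefficients normalized to sum to 1 (each basis profile has unit area per
#' unit abundance, so coefficients are directly comparable).
#'
#' @param observed A `mass_spectrum`.
#' @param candidates Non-empty list of `metal_complex` species.
#' @param z Charge state.
#' @param resolving_power FWHM resolving power for rendering.
#' @param prune,bin_width Passed to [isotope_pattern()].
#' @return A `mixture_result` list: `fractions` (named, summing to 1),
#'   `coefficients` (raw NNLS scales), `residual` (RMS).
#' @export
fit_mixture <- function(observed, candidates, z, resolving_power = 20000,
                        prune = 1e-10, bin_width = 1e-4) {
  stopifnot(inherits(observed, "mass_spectrum"))
  if (length(candidates) < 1) stop("need at least one candidate", call. = FALSE)
  rel_sigma <- 1 / (resolving_power * 2 * sqrt(2 * log(2)))
  basis <- vapply(candidates, function(sp) {
    pat <- to_mz(.cached_pattern(species_composition(sp), prune, bin_width), z)
    .render_on_grid(pat$mass, pat$abundance, rel_sigma, observed$mz)
  }, numeric(length(observed$mz)))
  basis <- matrix(basis, nrow = length(observed$mz))
  if (all(basis == 0)) {
    stop("singular basis: no candidate envelope overlaps the spectrum",
         call. = FALSE)
  }
  sol <- pracma::lsqnonneg(basis, observed$intensity)
  coef <- sol$x
  labels <- vapply(candidates, function(sp) sp$label, character(1))
  names(coef) <- labels
  total <- sum(coef)
  fractions <- if (total > 0) coef / total else coef
  resid <- sqrt(mean((observed$intensity - basis %*% coef)^2))
  structure(list(fractions = fractions, coefficients = coef,
                 residual = resid), class = "mixture_result")
}

#' @export
print.mixture_result <- function(x, ...) {
  cat("<mixture fit> residual RMS =", format(x$residual, digits = 4), "\n")
  print(round(x$fractions, 4))
  invisible(x)
}
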