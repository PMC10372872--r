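# Survival-yield analysis: center-of-mass energy normalization, survival
# yield, and sigmoid E50 extraction.

#' Center-of-mass collision energy
#'
#' `E_com = z * V_lab * m_gas / (m_gas + m_ion)` in eV, taking the lab-frame
#' energy as `z * V_trap` (singly-normalized electronvolts). Linear in both
#' `v_lab` and `z`; approaches `z * v_lab` as the gas mass grows.
#'
#' @param z Charge state (> 0).
#' @param v_lab Trap collision voltage (V, >= 0; vectorized).
#' @param gas_mass Collision gas mass in Da (argon = 39.948).
#' @param ion_mass Ion neutral mass in Da.
#' @return Energy in eV.
#' @examples
#' e_com(5, 30, 39.948, 7000)  # ~0.85 eV
#' @export
e_com <- function(z, v_lab, gas_mass, ion_mass) {
  if (z <= 0 || gas_mass <= 0 || ion_mass <= 0 || any(v_lab < 0)) {
    stop("charge, masses must be positive and voltages non-negative",
         call. = FALSE)
  }
  z * v_lab * gas_mass / (gas_mass + ion_mass)
}

#' Survival yield
#'
#' Fraction of precursor ions that did not fragment:
#' `precursor / (precursor + products)`. Invariant to simultaneous intensity
#' scaling.
#'
#' @param precursor_intensity Summed precursor intensity (>= 0; vectorized).
#' @param product_intensity Summed product intensity (>= 0).
#' @return Fraction in \[0, 1\].
#' @export
survival_yield <- function(precursor_intensity, product_intensity) {
  if (any(precursor_intensity < 0) || any(product_intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  total <- precursor_intensity + product_intensity
  if (any(total == 0)) {
    stop("precursor and product intensities are both zero", call. = FALSE)
  }
  precursor_intensity / total
}

#' Survival-yield curve container
#'
#' @param e_com Ascending center-of-mass energies (eV, >= 0).
#' @param sy Survival-yield fractions in \[0, 1\].
#' @param ion Ion label.
#' @return A `sy_curve` data.frame.
#' @export
sy_curve <- function(e_com, sy, ion = "") {
  if (length(e_com) != length(sy)) stop("length mismatch", call. = FALSE)
  if (any(e_com < 0) || any(diff(e_com) <= 0)) {
    stop("e_com must be non-negative and strictly ascending", call. = FALSE)
  }
  if (any(sy < 0 | sy > 1)) stop("sy must lie in [0, 1]", call. = FALSE)
  structure(data.frame(e_com = e_com, sy = sy),
            ion = ion, class = c("sy_curve", "data.frame"))
}

#' Fit a sigmoid to a survival-yield curve and extract E50
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of
#' `SY(E) = bottom + (top - bottom) / (1 + exp((E - e50) / w))`,
#' so SY falls from `top` at low energy to `bottom` at high energy and equals
#' `(top + bottom) / 2` at `E = e50`. Initial guesses: `e50` at the energy
#' whose SY is nearest 0.5, `w` a quarter of the energy span; asymptotes are
#' free but bounded in \[0, 1.2\].
#'
#' @param curve A `sy_curve` with >= 5 points spanning at least 0.5 of SY
#'   dynamic range.
#' @return A `sigmoid_fit` list: `e50`, `w`, `top`, `bottom`, `e50_se`,
#'   `residual_rms`, `converged`.
#' @export
fit_e50 <- function(curve) {
  stopifnot(inherits(curve, "sy_curve"))
  if (nrow(curve) < 5) stop("need at least 5 points", call. = FALSE)
  if (diff(range(curve$sy)) < 0.5) {
    stop("insufficient SY dynamic range (< 0.5) for a reliable midpoint",
         call. = FALSE)
  }
  span <- diff(range(curve$e_com))
  start <- list(e50 = curve$e_com[which.min(abs(curve$sy - 0.5))],
                w = span / 4, top = max(curve$sy), bottom = min(curve$sy))
  spacing <- stats::median(diff(curve$e_com))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      sy ~ bottom + (top - bottom) / (1 + exp((e_com - e50) / w)),
      data = curve, start = start,
      lower = c(e50 = min(curve$e_com) - spacing, w = 1e-6, top = 0,
                bottom = 0),
      upper = c(e50 = max(curve$e_com) + spacing, w = span, top = 1.2,
                bottom = 1.2),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("sigmoid fit did not converge: ", conditionMessage(e),
           call. = FALSE)
    })
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["e50", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(e50 = cf[["e50"]], w = cf[["w"]], top = cf[["top"]],
                 bottom = cf[["bottom"]], e50_se = se,
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 converged = fit$convInfo$isConv %||% TRUE),
            class = "sigmoid_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid fit> E50 = %.4f eV (se %.2g), w = %.4f eV, top %.3f, bottom %.3f\n",
              x$e50, x$e50_se, x$w, x$top, x$bottom))
  invisible(x)
}
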