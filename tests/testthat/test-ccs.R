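# Traveling-wave calibration, ATD -> CCS transformation, apex/FWHM summaries.

test_that("calibration recovers exact power-law coefficients", {
  cal <- make_exact_calibration(A = 200, B = 0.55, edc = 1.35)
  expect_equal(cal$A, 200, tolerance = 1e-9)
  expect_equal(cal$B, 0.55, tolerance = 1e-9)
  expect_gte(cal$r_squared, 1 - 1e-12)
  # round trip: every calibrant's reference CCS is reproduced
  expect_true(max(abs(cal$residuals)) < 1e-9)
})

test_that("calibration rejects degenerate or insufficient input", {
  tab <- tw_calibrants()
  few <- calibrant_entries(tab$name[1:2], tab$charge[1:2], tab$mass[1:2],
                           tab$ccs_ref[1:2], c(5, 6))
  expect_error(calibrate_tw(few, edc = 1.35), "at least 3")
  same_t <- calibrant_entries(tab$name[1:3], tab$charge[1:3], tab$mass[1:3],
                              tab$ccs_ref[1:3], rep(5, 3))
  expect_error(calibrate_tw(same_t, edc = 0), "degenerate")
  neg_t <- calibrant_entries(tab$name[1:3], tab$charge[1:3], tab$mass[1:3],
                             tab$ccs_ref[1:3], c(0.01, 5, 6))
  expect_error(calibrate_tw(neg_t, edc = 10), "non-positive corrected")
})

test_that("edc = 0 leaves drift times uncorrected", {
  cal0 <- make_exact_calibration(edc = 0)
  a <- atd(c(5, 6, 7), c(1, 2, 1), mass = 6990, charge = 5)
  d <- atd_to_ccs(a, cal0, smooth_sigma = 0)
  mu <- 6990 * N2_MASS / (6990 + N2_MASS)
  expect_equal(d$ccs, cal0$A * c(5, 6, 7)^cal0$B * 5 / sqrt(mu),
               tolerance = 1e-12)
  # monotone: larger arrival time -> larger CCS for B > 0
  expect_true(all(diff(d$ccs) > 0))
})

test_that("ATD transformation preserves modes and apex ordering", {
  cal <- make_exact_calibration()
  tg <- seq(4, 16, length.out = 600)
  g1 <- atd(tg, dnorm(tg, 8, 0.5), mass = 6990, charge = 5)
  d1 <- atd_to_ccs(g1, cal)
  # apex equals the transform of the ATD mode within a grid step
  mu <- 6990 * N2_MASS / (6990 + N2_MASS)
  mz <- (6990 + 5 * 1.007276) / 5
  expected <- cal$A * (8 - cal$edc * sqrt(mz) / 1000)^cal$B * 5 / sqrt(mu)
  expect_equal(d1$apex, expected, tolerance = 1e-3)
  # bimodal ATD -> bimodal CCS distribution
  g2 <- atd(tg, dnorm(tg, 8, 0.5) + 0.8 * dnorm(tg, 12, 0.6),
            mass = 6990, charge = 5)
  d2 <- atd_to_ccs(g2, cal)
  y <- metims:::.smooth_gauss(d2$intensity, 2)
  n <- length(y)
  modes <- sum(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n] &
                 y[2:(n - 1)] > 0.05 * max(y))
  expect_equal(modes, 2)
  # apex ordering preserved for ions at equal m/z and charge
  g3 <- atd(tg, dnorm(tg, 9, 0.5), mass = 6990, charge = 5)
  expect_lt(d1$apex, atd_to_ccs(g3, cal)$apex)
  # mismatched TW parameter sets are refused
  cal_a <- make_exact_calibration(tw_set = "300ms 20V")
  atd_b <- atd(tg, dnorm(tg, 8, 0.5), mass = 6990, charge = 5,
               tw_set = "480ms 20V")
  expect_error(atd_to_ccs(atd_b, cal_a), "mismatch")
})

test_that("summaries report Gaussian FWHM and scale invariance", {
  ccs <- seq(800, 1200, by = 1)
  y <- dnorm(ccs, 1000, 20)
  s <- summarize_ccs(list(ccs = ccs, intensity = y), smooth_sigma = 0)
  expect_equal(s[["apex"]], 1000, tolerance = 1)
  expect_equal(s[["fwhm"]], 2 * sqrt(2 * log(2)) * 20, tolerance = 0.1)
  s10 <- summarize_ccs(list(ccs = ccs, intensity = 10 * y), smooth_sigma = 0)
  expect_identical(s, s10)
  # delta-like single bin reports one grid step
  spike <- rep(0, length(ccs)); spike[200] <- 1
  sd0 <- summarize_ccs(list(ccs = ccs, intensity = spike), smooth_sigma = 0)
  expect_equal(sd0[["fwhm"]], 1, tolerance = 1e-6)
  expect_error(summarize_ccs(list(ccs = ccs, intensity = rep(0, length(ccs)))),
               "all-zero")
})
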