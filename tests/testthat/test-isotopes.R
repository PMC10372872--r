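# Isotopic pattern simulation, m/z transformation and profile rendering.

test_that("single-element patterns reproduce the bundled abundance table", {
  h <- isotope_pattern(ec(H = 1))
  expect_equal(h$mass, c(1.0078250319, 2.0141017781))
  expect_equal(h$abundance, c(0.999885, 0.000115))
  zn <- isotope_pattern(ec(Zn = 1))
  tab <- isotope_table()
  zn_tab <- tab[tab$element == "Zn", ]
  expect_equal(zn$mass, zn_tab$mass)
  expect_equal(zn$abundance, zn_tab$abundance, tolerance = 1e-12)
})

test_that("H2 pattern matches the three-outcome enumeration", {
  h2 <- isotope_pattern(ec(H = 2))
  i <- which.max(h2$abundance)
  expect_equal(h2$mass[i], 2 * 1.0078250319, tolerance = 1e-9)
  expect_equal(h2$abundance[i], 0.999885^2, tolerance = 1e-12)
  expect_equal(length(h2$mass), 3)
})

test_that("patterns agree with the brute-force multinomial oracle", {
  expect_pattern_matches_oracle(ec(H = 2, O = 1))
  expect_pattern_matches_oracle(ec(C = 3, H = 5, N = 1, O = 1, S = 1))
  expect_pattern_matches_oracle(ec(Cu = 1, Zn = 1))
  expect_pattern_matches_oracle(ec(Zn = 2, S = 2))
})

test_that("patterns are normalized, sorted, and conserve abundance", {
  comps <- list(ec(C = 50, H = 80, N = 10, O = 15, S = 2),
                ec(C = 259, H = 413, N = 77, O = 102, S = 21, Cu = 4, Zn = 4))
  for (comp in comps) {
    p <- isotope_pattern(comp)
    expect_equal(sum(p$abundance), 1, tolerance = 1e-9)
    expect_true(all(diff(p$mass) > 0))
    expect_gte(p$retained, 0.999)
  }
})

test_that("convolution identity: pattern(A+B) equals pattern(A) x pattern(B)", {
  a <- ec(C = 10, H = 15, N = 3, O = 4)
  b <- ec(S = 2, Zn = 1)
  pab <- isotope_pattern(a + b)
  pa <- isotope_pattern(a)
  pb <- isotope_pattern(b)
  m <- as.vector(outer(pa$mass, pb$mass, "+"))
  w <- as.vector(outer(pa$abundance, pb$abundance))
  o <- order(m)
  manual <- .new_pattern_for_test(m[o], w[o])
  # compare as rendered profiles: insensitive to how sticks split across
  # adjacent mass bins, faithful to the pattern shape
  grid <- seq(min(pab$mass) - 0.2, max(pab$mass) + 0.2, by = 2e-4)
  y1 <- render_profile(to_mz(pab, 1), resolving_power = 50000,
                       grid = grid + 1.007276)$intensity
  y2 <- render_profile(to_mz(manual, 1), resolving_power = 50000,
                       grid = grid + 1.007276)$intensity
  expect_lt(max(abs(y1 - y2)) / max(y1), 1e-6)
})

test_that("to_mz applies the proton transform and enforces the domain", {
  p <- .new_pattern_for_test(6900, 1)
  p5 <- to_mz(p, 5)
  expect_equal(p5$mass, (6900 + 5 * 1.007276) / 5, tolerance = 1e-9)
  expect_equal(p5$mass, 1381.007276, tolerance = 1e-6)
  p1 <- to_mz(p, 1)
  expect_equal(p1$mass, 6901.007276, tolerance = 1e-9)
  expect_error(to_mz(p5, 2), "already")
  expect_error(to_mz(p, 0), "positive integer")
  expect_error(to_mz(p, -3), "positive integer")
})

test_that("rendered profiles have abundance-proportional areas and FWHM", {
  # single stick: integral of the profile equals the abundance
  prof <- render_profile(to_mz(.new_pattern_for_test(4995, 1), 5),
                         resolving_power = 20000)
  area <- pracma::trapz(prof$mz, prof$intensity)
  expect_equal(area, 1, tolerance = 1e-3)
  # doubling resolving power halves the FWHM
  fwhm_of <- function(rp) {
    s <- render_profile(to_mz(.new_pattern_for_test(4995, 1), 5),
                        resolving_power = rp, grid_step = 1e-4)
    half <- max(s$intensity) / 2
    rng <- range(s$mz[s$intensity >= half])
    diff(rng)
  }
  expect_equal(fwhm_of(10000) / fwhm_of(20000), 2, tolerance = 0.01)
  # two sticks 10 FWHM apart resolve into two local maxima
  fwhm <- 1000 / 20000
  p2 <- to_mz(.new_pattern_for_test(c(1000, 1000 + 10 * fwhm) * 3 -
                                      3 * 1.007276, c(0.5, 0.5)), 3)
  s <- render_profile(p2, resolving_power = 20000)
  y <- s$intensity
  n <- length(y)
  maxima <- sum(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n] &
                  y[2:(n - 1)] > max(y) * 0.1)
  expect_equal(maxima, 2)
  expect_error(render_profile(p2, grid_step = -1), "positive")
  expect_error(render_profile(.new_pattern_for_test(100, 1)), "m/z")
})
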