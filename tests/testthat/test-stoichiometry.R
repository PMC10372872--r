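# Candidate enumeration, envelope scoring, species assignment, mixture fits.

test_that("candidate enumeration covers the grid and honors constraints", {
  mt3 <- mt3_sequence()
  free <- enumerate_candidates(candidate_grid(0:1, 0:1, 0), mt3)
  expect_length(free, 4)
  expect_equal(vapply(free, function(s) s$n_cu, integer(1)), c(0L, 0L, 1L, 1L))
  # lexicographic (n_cu, n_zn, n_ss) order
  full <- enumerate_candidates(candidate_grid(), mt3)
  key <- vapply(full, function(s) s$n_cu * 100 + s$n_zn * 10 + s$n_ss,
                numeric(1))
  expect_true(all(diff(key) > 0))
  for (s in full) {
    expect_lte(s$n_cu + s$n_zn + 2 * s$n_ss, 20)
    expect_lte(s$n_h, 20)
  }
  # mass window filter
  target <- average_mass(species_composition(metal_complex(mt3, 4, 4, 2)))
  near <- enumerate_candidates(
    candidate_grid(0:8, 0:7, 0:2, mass_target = target, mass_window = 5), mt3)
  for (s in near) {
    expect_lte(abs(average_mass(species_composition(s)) - target), 5)
  }
  expect_warning(
    enumerate_candidates(
      candidate_grid(8, 7, 2, mass_target = 0, mass_window = 1), mt3),
    "no candidate")
})

test_that("score_fit gives a perfect self-match and penalizes a 2H shift", {
  mt3 <- mt3_sequence()
  sp <- metal_complex(mt3, 4, 4, 2)
  obs <- synth_spectrum(sp, charges = 5)
  pat <- to_mz(isotope_pattern(species_composition(sp)), 5)
  self <- score_fit(pat, obs, 5)
  expect_gte(self$score, 0.999)
  # one fewer disulfide = +2 H: overlapping but distinguishable envelope
  pat2 <- to_mz(isotope_pattern(species_composition(metal_complex(mt3, 4, 4, 1))), 5)
  other <- score_fit(pat2, obs, 5)
  expect_lt(other$score, self$score)
  # scale invariance of the score
  obs10 <- mass_spectrum(obs$mz, obs$intensity * 17.3)
  expect_equal(score_fit(pat, obs10, 5)$score, self$score, tolerance = 1e-9)
  # degenerate inputs
  flat <- mass_spectrum(obs$mz, rep(0, length(obs$mz)))
  expect_error(score_fit(pat, flat, 5), "empty")
  far <- mass_spectrum(seq(100, 200, 0.01), rep(1, 10001))
  expect_error(score_fit(pat, far, 5), "overlap")
  expect_error(score_fit(pat, obs, 4), "charge")
})

test_that("score_fit recovers a small global m/z calibration offset", {
  mt3 <- mt3_sequence()
  sp <- metal_complex(mt3, n_zn = 7)
  obs <- synth_spectrum(sp, charges = 5)
  shifted <- mass_spectrum(obs$mz + 0.02, obs$intensity)
  pat <- to_mz(isotope_pattern(species_composition(sp)), 5)
  fit <- score_fit(pat, shifted, 5)
  expect_equal(fit$mz_shift, 0.02, tolerance = 2e-3)
  expect_gte(fit$score, 0.999)
  expect_lte(abs(fit$mz_shift), 0.05)
})

test_that("assign_species ranks the generating species first", {
  mt3 <- mt3_sequence()
  grid <- candidate_grid(3:5, 3:5, 0:2)
  apo_obs <- synth_spectrum(metal_complex(mt3), charges = 5)
  res0 <- assign_species(apo_obs, candidate_grid(0:1, 0:1, 0:1), mt3, 5)
  expect_equal(unlist(res0[1, c("n_cu", "n_zn", "n_ss")], use.names = FALSE),
               c(0, 0, 0))
  obs <- synth_spectrum(metal_complex(mt3, 4, 4, 2), charges = 5)
  res <- assign_species(obs, grid, mt3, 5)
  expect_equal(unlist(res[1, c("n_cu", "n_zn", "n_ss")], use.names = FALSE),
               c(4, 4, 2))
  expect_gt(attr(res, "margin"), 0)
  expect_true(all(diff(res$score[!is.na(res$score)]) <= 1e-9))
})

test_that("mixture NNLS recovers fractions and flags missing species", {
  mt3 <- mt3_sequence()
  zn7 <- metal_complex(mt3, n_zn = 7)
  cuzn <- metal_complex(mt3, 4, 4, 2)
  mix <- synth_spectrum(list(zn7, cuzn), fractions = c(0.7, 0.3), charges = 5)
  fit <- fit_mixture(mix, list(zn7, cuzn), 5)
  expect_equal(unname(fit$fractions), c(0.7, 0.3), tolerance = 0.01)
  # single species against a two-candidate basis: second abundance vanishes
  pure <- synth_spectrum(zn7, charges = 5)
  fit1 <- fit_mixture(pure, list(zn7, cuzn), 5)
  expect_lte(fit1$fractions[[2]], 1e-6)
  # dropping the true species strictly increases the residual
  with_true <- fit_mixture(mix, list(zn7, cuzn), 5)$residual
  without <- fit_mixture(mix, list(zn7, metal_complex(mt3, 4, 3, 2)), 5)$residual
  expect_gt(without, with_true)
  expect_error(fit_mixture(mix, list(), 5), "at least one")
})
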