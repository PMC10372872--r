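# b/y fragment generation with metal adducts, ppm matching, localization.

test_that("fragment masses match hand-computed references", {
  y1 <- generate_fragments(protein_sequence("GK"), 1)
  expect_equal(y1$mz[y1$series == "y" & y1$index == 1], 147.1128,
               tolerance = 1e-4)
  b2 <- generate_fragments(protein_sequence("MDP"), 1)
  expect_equal(b2$mz[b2$series == "b" & b2$index == 2], 247.0747,
               tolerance = 1e-4)
  expect_error(generate_fragments(protein_sequence("G"), 1), "at least 2")
})

test_that("metal adducts shift fragments by the displacement model", {
  mt3 <- mt3_sequence()
  fr <- generate_fragments(mt3, max_charge = 1, zn = 0:1)
  y30_0 <- fr[fr$series == "y" & fr$index == 30 & fr$n_zn == 0, ]
  y30_zn <- fr[fr$series == "y" & fr$index == 30 & fr$n_zn == 1, ]
  m_zn <- monoisotopic_mass(ec(Zn = 1))
  m_h <- monoisotopic_mass(ec(H = 1))
  expect_equal(y30_zn$neutral_mass - y30_0$neutral_mass, m_zn - 2 * m_h,
               tolerance = 1e-9)
  # disulfide variants differ by 2 H
  fr_ss <- generate_fragments(mt3, max_charge = 1, ss = 0:2)
  y30 <- fr_ss[fr_ss$series == "y" & fr_ss$index == 30, ]
  expect_equal(nrow(y30), 3)  # the three disulfide-count variants
  expect_equal(diff(sort(y30$neutral_mass, decreasing = TRUE)),
               rep(-2 * m_h, 2), tolerance = 1e-9)
  # cysteine budget prunes impossible adduct states: y1 (Q, no Cys) takes none
  y1 <- fr[fr$series == "y" & fr$index == 1, ]
  expect_equal(y1$n_zn, 0L)
})

test_that("b/y complementarity reconstructs the precursor mass", {
  mt3 <- mt3_sequence()
  fr <- generate_fragments(mt3, max_charge = 1)
  L <- length(mt3)
  neutral_full <- monoisotopic_mass(composition_from_sequence(mt3))
  b <- fr[fr$series == "b", ]
  y <- fr[fr$series == "y", ]
  for (i in c(1, 10, 31, 67)) {
    bi <- b$neutral_mass[b$index == i]
    yi <- y$neutral_mass[y$index == L - i]
    expect_equal(bi + yi, neutral_full, tolerance = 1e-9)
  }
})

test_that("ppm matching is tolerance-bounded, greedy, one-to-one", {
  frag <- data.frame(series = "y", index = 1:2, charge = 1L, n_cu = 0L,
                     n_zn = 0L, n_ss = 0L, water_loss = 0L,
                     neutral_mass = c(999, 1999), mz = c(1000, 2000))
  class(frag) <- c("fragment_ions", "data.frame")
  peaks <- data.frame(mz = c(1000.015, 2000.06), intensity = c(5, 3))
  m <- match_fragments(peaks, frag, tol_ppm = 20)
  expect_equal(nrow(m), 1)  # the 30 ppm peak is rejected
  expect_equal(m$ppm_error, 15, tolerance = 1e-6)
  expect_true(all(abs(m$ppm_error) <= 20))
  # empty inputs are allowed
  expect_equal(nrow(match_fragments(peaks[0, ], frag, 20)), 0)
})

test_that("planted fragments are all matched and decoys are not", {
  mt3 <- mt3_sequence()
  fr <- generate_fragments(mt3, max_charge = 3, zn = 0:1, ss = 0:2,
                           water_loss = TRUE)
  plant <- fr[fr$series == "y" & fr$index %in% seq(2, 60, 2) &
                fr$charge == 1 & fr$n_zn == 0 & fr$n_ss == 0 &
                fr$water_loss == 0, ][1:30, ]
  pk <- synth_fragment_peaks(plant, all_theoretical = fr, ppm_jitter = 4,
                             n_decoys = 100, seed = 42)
  m <- match_fragments(pk, fr, tol_ppm = 20)
  planted_mz <- pk$mz[!pk$is_decoy]
  expect_equal(sum(m$observed_mz %in% planted_mz), 30)
  expect_equal(sum(m$observed_mz %in% pk$mz[pk$is_decoy]), 0)
  expect_true(all(abs(m$ppm_error) <= 20))
})

test_that("metal-free y-series evidence confines metals to the N-terminus", {
  mt3 <- mt3_sequence()
  fr <- generate_fragments(mt3, max_charge = 1)
  matches <- fr[fr$series == "y" & fr$index %in% 2:30, ]
  matches$observed_mz <- matches$mz
  matches$ppm_error <- 0
  matches$intensity <- 1
  class(matches) <- c("fragment_matches", "data.frame")
  loc <- localize_metals(matches, 68, boundary = 38)
  cu <- loc[loc$metal == "Cu", ]
  expect_equal(cu$interval_start, 1)
  expect_equal(cu$interval_end, 38)
  expect_true(cu$within_beta)
  expect_false(cu$inconsistent)
})

test_that("localization handles vacuous and partially metalated evidence", {
  empty <- match_fragments(data.frame(mz = numeric(0), intensity = numeric(0)),
                           generate_fragments(protein_sequence("GK"), 1), 20)
  loc0 <- localize_metals(empty, 68, boundary = 31)
  expect_equal(loc0$interval_start, c(1, 1))
  expect_equal(loc0$interval_end, c(68, 68))
  # coexisting Zn-free and Zn1 y30 (two populations): the suffix stays inside
  # the Zn interval and no inconsistency is flagged
  mt3 <- mt3_sequence()
  fr <- generate_fragments(mt3, max_charge = 1, zn = 0:1)
  both <- fr[fr$series == "y" & fr$index == 30, ]
  both$observed_mz <- both$mz; both$ppm_error <- 0; both$intensity <- 1
  class(both) <- c("fragment_matches", "data.frame")
  loc <- localize_metals(both, 68, boundary = 31)
  zn <- loc[loc$metal == "Zn", ]
  expect_equal(zn$interval_end, 68)  # suffix not excluded for Zn
  expect_false(zn$inconsistent)
  # but a metal-bearing ion strictly inside a longer metal-free suffix is
  # reported via the inconsistency flag
  odd <- fr[fr$series == "y" & ((fr$index == 30 & fr$n_zn == 0) |
                                  (fr$index == 10 & fr$n_zn == 1)), ]
  odd$observed_mz <- odd$mz; odd$ppm_error <- 0; odd$intensity <- 1
  class(odd) <- c("fragment_matches", "data.frame")
  loc2 <- localize_metals(odd, 68, boundary = 31)
  expect_true(loc2[loc2$metal == "Zn", "inconsistent"])
  expect_error(localize_metals(empty, 68, boundary = 0), "boundary")
})

test_that("localization intervals always contain the true metal region", {
  # property sweep: metals planted in residues [1, 31]; evidence model only
  # produces metal-free fragments that avoid the metal region
  mt3 <- mt3_sequence()
  L <- length(mt3)
  fr <- generate_fragments(mt3, max_charge = 1, cu = 0:1, zn = 0:1)
  set.seed(2024)
  for (rep in 1:100) {
    true_lo <- 1; true_hi <- 31
    y_idx <- sort(sample(2:(L - 1), sample(5:20, 1)))
    rows <- lapply(y_idx, function(k) {
      covers_metal <- (L - k + 1) <= true_hi
      if (covers_metal && stats::runif(1) > 0.7) return(NULL)  # ion not seen
      sel <- fr$series == "y" & fr$index == k &
        fr$n_cu == as.integer(covers_metal) & fr$n_zn == 0
      fr[sel, ][1, ]
    })
    matches <- do.call(rbind, rows)
    if (is.null(matches) || nrow(matches) == 0) next
    matches <- matches[!is.na(matches$index), ]
    matches$observed_mz <- matches$mz; matches$ppm_error <- 0
    matches$intensity <- 1
    class(matches) <- c("fragment_matches", "data.frame")
    loc <- localize_metals(matches, L, boundary = 31)
    cu <- loc[loc$metal == "Cu", ]
    expect_lte(cu$interval_start, true_lo)
    expect_gte(cu$interval_end, true_hi)
  }
})
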