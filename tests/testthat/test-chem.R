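# Elemental compositions, protein/metal-complex species, and masses.

test_that("compositions from sequences follow residue + water bookkeeping", {
  expect_equal(format_formula(composition_from_sequence("G")), "H5C2NO2")
  gg <- composition_from_sequence("GG")
  expect_equal(unclass(gg)[c("C", "H", "N", "O")],
               c(C = 4L, H = 8L, N = 2L, O = 3L))
  expect_error(protein_sequence(""), "length")
  expect_error(protein_sequence("GXG"), "position 2")
})

test_that("composition arithmetic is element-wise and guards negatives", {
  a <- ec(C = 2, H = 5, N = 1, O = 2)
  b <- ec(H = 2, O = 1, S = 1)
  s <- a + b
  expect_equal(unclass(s)[c("C", "H", "N", "O", "S")],
               c(C = 2L, H = 7L, N = 1L, O = 3L, S = 1L))
  expect_equal(unclass(s - b), unclass(a))
  expect_error(b - a, "negative")
  expect_error(ec(Xx = 1), "unknown element")
  expect_error(ec(H = -1), "non-negative")
  expect_equal(unclass(2 * b)[["H"]], 4L)
})

test_that("mass functions are additive and match reference values", {
  expect_equal(average_mass(ec(Cu = 1)), 63.546, tolerance = 1e-4)
  expect_equal(average_mass(ec(Zn = 1)), 65.38, tolerance = 1e-3)
  # the Cu/Zn distinction the envelope fitting has to resolve: 1.8 Da average
  expect_equal(round(average_mass(ec(Zn = 1)) - average_mass(ec(Cu = 1)), 1),
               1.8)
  expect_equal(monoisotopic_mass(ec(H = 2, O = 1)), 18.0106, tolerance = 1e-4)
  expect_equal(monoisotopic_mass(ec(Cu = 1)), 62.9296, tolerance = 1e-4)
  expect_equal(monoisotopic_mass(ec()), 0)
  a <- composition_from_sequence("ACDEFGHIK")
  b <- ec(C = 10, H = 7, N = 2, S = 3)
  expect_equal(average_mass(a + b), average_mass(a) + average_mass(b),
               tolerance = 1e-12)
  expect_equal(monoisotopic_mass(a + b),
               monoisotopic_mass(a) + monoisotopic_mass(b), tolerance = 1e-12)
  # monoisotopic never exceeds average by more than the sanity envelope
  for (comp in list(a, b, ec(Cu = 3, Zn = 4), ec(S = 10))) {
    expect_lte(monoisotopic_mass(comp), average_mass(comp) * (1 + 1e-3))
  }
})

test_that("hydrogen-displacement model yields the expected species masses", {
  mt3 <- mt3_sequence()
  expect_equal(length(mt3), 68)
  expect_equal(n_cys(mt3), 20)
  apo <- composition_from_sequence(mt3)
  # all-zero species is exactly the apo reduced composition
  expect_identical(unclass(species_composition(metal_complex(mt3))),
                   unclass(apo))
  expect_equal(metal_complex(mt3, n_zn = 7)$n_h, 14)
  expect_equal(metal_complex(mt3, 4, 4, 2)$n_h, 16)
  zn7 <- species_composition(metal_complex(mt3, n_zn = 7))
  expect_equal(unclass(zn7)[["H"]], unclass(apo)[["H"]] - 14L)
  # one extra disulfide removes exactly two hydrogens
  m_h <- monoisotopic_mass(ec(H = 2)) / 2
  for (s in 0:1) {
    lo <- species_composition(metal_complex(mt3, 4, 4, s))
    hi <- species_composition(metal_complex(mt3, 4, 4, s + 1))
    expect_equal(monoisotopic_mass(lo) - monoisotopic_mass(hi), 2 * m_h,
                 tolerance = 1e-9)
  }
})

test_that("thiol and hydrogen budgets reject impossible species", {
  mt3 <- mt3_sequence()
  expect_error(metal_complex(mt3, n_cu = 8, n_zn = 7, n_ss = 2), "thiol protons")
  expect_error(metal_complex(mt3, n_cu = 18, n_zn = 0, n_ss = 2),
               "thiol budget")
  # budgets can be relaxed explicitly
  expect_s3_class(metal_complex(mt3, 8, 7, 2, check_budget = FALSE),
                  "metal_complex")
})
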