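# Shared fixtures built in code: an exact synthetic TW calibration and a
# brute-force isotopologue enumerator used as the independent oracle.

N2_MASS <- 28.0134

# calibration whose entries are generated exactly from (A, B, edc): the
# bundled calibrant table supplies (mass, charge, reference CCS); arrival
# times are back-calculated through the power law.
make_exact_calibration <- function(A = 200, B = 0.55, edc = 1.35,
                                   gas_mass = N2_MASS, tw_set = NULL) {
  tab <- tw_calibrants()
  mu <- tab$mass * gas_mass / (tab$mass + gas_mass)
  ccs_prime <- tab$ccs_ref * sqrt(mu) / tab$charge
  tprime <- (ccs_prime / A)^(1 / B)
  mz <- (tab$mass + tab$charge * 1.007276) / tab$charge
  entries <- calibrant_entries(tab$name, tab$charge, tab$mass, tab$ccs_ref,
                               tprime + edc * sqrt(mz) / 1000)
  calibrate_tw(entries, edc = edc, gas_mass = gas_mass, tw_set = tw_set)
}

# Independent oracle: enumerate every per-atom isotope assignment of a small
# composition (brute-force multinomial expansion), aggregating identical
# outcomes at 1e-6 Da. Only feasible for <= ~10 atoms.
brute_force_pattern <- function(comp) {
  comp <- as_elemental_composition(comp)
  tab <- isotope_table()
  choice_rows <- list()
  for (el in names(comp)) {
    rows <- which(tab$element == el)
    for (i in seq_len(comp[[el]])) choice_rows[[length(choice_rows) + 1]] <- rows
  }
  grid <- as.matrix(expand.grid(choice_rows, KEEP.OUT.ATTRS = FALSE))
  mass <- rowSums(matrix(tab$mass[grid], nrow = nrow(grid)))
  ab <- exp(rowSums(matrix(log(tab$abundance[grid]), nrow = nrow(grid))))
  key <- round(mass * 1e6)
  ab2 <- rowsum(ab, key)
  m2 <- rowsum(ab * mass, key) / ab2
  o <- order(m2)
  list(mass = as.numeric(m2)[o], abundance = as.numeric(ab2)[o] / sum(ab2))
}

# build a neutral-mass stick pattern directly (test scaffolding)
.new_pattern_for_test <- function(mass, abundance) {
  metims:::.new_pattern(mass, abundance / sum(abundance))
}

# compare a package pattern with the oracle entry-by-entry; both sides are
# aggregated at 1e-6 Da, far below the spacing of distinct isotopologues but
# above floating-point summation noise
expect_pattern_matches_oracle <- function(comp, mass_tol = 1e-9,
                                          ab_tol = 1e-12) {
  p <- isotope_pattern(comp, prune = 0, bin_width = 1e-6)
  o <- brute_force_pattern(comp)
  expect_equal(length(p$mass), length(o$mass))
  expect_true(max(abs(p$mass - o$mass)) < mass_tol)
  expect_true(max(abs(p$abundance - o$abundance)) < ab_tol)
}
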