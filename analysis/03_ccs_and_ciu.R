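#!/usr/bin/env Rscript
# Ion-mobility analysis: calibrate the traveling-wave device against the
# bundled protein calibrants, transform simulated arrival-time distributions
# of the 5+ ions to CCS space (apexes programmed at the observed 1069 and
# 990 A^2 conformations), and build a CIU fingerprint with its compact:
# extended conformer trajectory. Writes CCS summaries and the fingerprint
# matrix under results/.

suppressPackageStartupMessages(library(metims))
dir.create("results", showWarnings = FALSE)

mt3 <- mt3_sequence()

## TW calibration: synthetic arrival times generated exactly from a known
## power law (A = 200, B = 0.55, EDC = 1.35), then refit
tab <- tw_calibrants()
A0 <- 200; B0 <- 0.55; edc0 <- 1.35; gas <- 28.0134
mu <- tab$mass * gas / (tab$mass + gas)
tprime <- ((tab$ccs_ref * sqrt(mu) / tab$charge) / A0)^(1 / B0)
mz <- (tab$mass + tab$charge * 1.007276) / tab$charge
entries <- calibrant_entries(tab$name, tab$charge, tab$mass, tab$ccs_ref,
                             tprime + edc0 * sqrt(mz) / 1000)
cal <- calibrate_tw(entries, edc = edc0, gas_mass = gas, tw_set = "300ms 20V")
print(cal)
message(sprintf("max relative calibrant residual: %.2e", max(abs(cal$residuals))))

## CCS distributions of the two complexes (5+), single native conformer
zn7 <- metal_complex(mt3, n_zn = 7, label = "Zn7MT3red")
cuzn <- metal_complex(mt3, 4, 4, 2, label = "Cu4Zn4MT3ox")
summaries <- list()
for (cond in list(list(sp = zn7, ccs = 1069, width = 40),
                  list(sp = cuzn, ccs = 990, width = 22))) {
  m <- average_mass(species_composition(cond$sp))
  t0 <- ccs_to_time(cond$ccs, cal, m, 5)
  dt <- ccs_to_time(cond$ccs + cond$width, cal, m, 5) - t0
  tg <- seq(max(t0 - 6 * dt, 1e-3), t0 + 6 * dt, length.out = 500)
  a <- atd(tg, dnorm(tg, t0, dt), mass = m, charge = 5,
           label = cond$sp$label, tw_set = "300ms 20V")
  d <- atd_to_ccs(a, cal)
  print(d)
  summaries[[cond$sp$label]] <- data.frame(species = cond$sp$label, charge = 5,
                                           apex = d$apex, fwhm = d$fwhm)
}
write_results(do.call(rbind, summaries), "results/ccs_summaries.csv")

## CIU fingerprint of the Zn7 5+ ion: logistic compact->extended transition
m_zn7 <- average_mass(species_composition(zn7))
atds <- synth_ciu(cal, mass = m_zn7, charge = 5, midpoint_ce = 30,
                  logistic_width = 3, compact_ccs = 1000, extended_ccs = 1300,
                  label = "Zn7MT3red")
fp <- build_fingerprint(atds, cal)
print(fp)
b <- find_boundary(fp)
ef <- extended_fraction(fp, b)
message(sprintf("compact/extended boundary: %.0f A^2", b))
message(sprintf("transition CE (extended > 50%%): %s V", transition_ce(fp, b)))
fpm <- as.data.frame(fp$matrix)
names(fpm) <- paste0("ce_", fp$ce_axis, "V")
write_results(cbind(data.frame(ccs = fp$ccs_axis), fpm),
              "results/ciu_fingerprint.csv")
write_results(data.frame(ce = fp$ce_axis, extended_fraction = ef,
                         compact_fraction = 1 - ef),
              "results/ciu_conformer_fractions.csv")
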