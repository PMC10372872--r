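#!/usr/bin/env Rscript
# Simulate the native mass spectra that drive the stoichiometry analysis:
# isotopically resolved 5+/4+ envelopes of the Zn7 (reduced) starting complex,
# the Cu4Zn4 (two-disulfide) product, and a 70:30 reaction-intermediate
# mixture in which the two envelopes overlap. Writes two-column text spectra
# plus a ground-truth manifest under results/spectra/.

suppressPackageStartupMessages(library(metims))

out_dir <- "results/spectra"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

mt3 <- mt3_sequence()
zn7 <- metal_complex(mt3, n_zn = 7, label = "Zn7MT3red")
cuzn <- metal_complex(mt3, 4, 4, 2, label = "Cu4Zn4MT3ox")
cu4 <- metal_complex(mt3, 4, 0, 2, label = "Cu4MT3ox")

message("Species masses (average Da):")
for (sp in list(zn7, cuzn, cu4)) {
  message(sprintf("  %-12s %.2f", sp$label,
                  average_mass(species_composition(sp))))
}

write_spec <- function(spec, file) {
  writeLines(c("# m/z intensity",
               sprintf("%.6f %.6g", spec$mz, spec$intensity)),
             file.path(out_dir, file))
}

manifest <- list()
for (z in c(4, 5)) {
  for (sp in list(zn7, cuzn)) {
    s <- synth_spectrum(sp, charges = z)
    f <- sprintf("%s_%dplus.txt", sp$label, z)
    write_spec(s, f)
    manifest[[f]] <- list(species = sp$label, n_cu = sp$n_cu, n_zn = sp$n_zn,
                          n_ss = sp$n_ss, charge = z, noise_sd = 0)
  }
}
# overlapping-envelope mixture at 5+ (70% Zn7, 30% Cu4Zn4), 1% noise
mix <- synth_spectrum(list(zn7, cuzn), fractions = c(0.7, 0.3), charges = 5,
                      noise_sd = 0.01, seed = 20230713)
write_spec(mix, "mixture_70_30_5plus.txt")
manifest[["mixture_70_30_5plus.txt"]] <- list(
  species = c("Zn7MT3red", "Cu4Zn4MT3ox"), fractions = c(0.7, 0.3),
  charge = 5, noise_sd = 0.01, seed = 20230713)

jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
message("wrote ", length(manifest), " spectra + manifest to ", out_dir)
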