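# metims — native ion-mobility mass spectrometry of metalloprotein complexes

`metims` is an R toolkit for characterizing metal–protein complexes by
native mass spectrometry, built around the chemistry of brain
metallothionein-3 (MT3): the reaction of the fully reduced Zn(II)₇ complex
with Cu(II), which reduces copper to Cu(I), displaces zinc, forms
intramolecular disulfides, and ends at a Cu(I)₄Zn(II)₄ complex with two
disulfides and the copper confined to the N-terminal β-domain.

It is aimed at native-MS practitioners who need the computational half of
that experiment:

* **Isotope simulation** — exact isotopic fine-structure patterns for any
  H/C/N/O/S/Cu/Zn composition (per-element convolution, 1e-4 Da binning,
  1e-10 pruning), rendered as resolution-limited profiles.
* **Stoichiometry assignment** — candidate species `(n_Cu, n_Zn, n_SS)` are
  enumerated under cysteine budgets with the charge-neutral
  hydrogen-displacement mass model `n_H = n_Cu + 2 n_Zn + 2 n_SS`, their
  theoretical envelopes fitted to the observed spectrum (cosine score, a
  bounded global m/z shift, parsimony tie-breaks), and ranked; overlapping
  species are decomposed by non-negative least squares.
* **TW-CCS calibration** — the standard power-law protocol
  (`CCS·√μ/z = A·t'^B`, EDC-corrected drift times) against bundled protein
  calibrants, with arrival-time → CCS transformation and apex/FWHM
  summaries.
* **Collision-induced unfolding** — CE × CCS fingerprints with per-column
  normalization, automatic compact/extended boundary detection, and
  conformer-ratio trajectories.
* **Survival-yield stability** — center-of-mass energy normalization
  `E_com = z·V·m_gas/(m_gas+m_ion)`, survival yield
  `SY = precursor/(precursor+products)`, and sigmoid fits whose midpoint
  E50 ranks gas-phase stability.
* **Top-down annotation** — b/y fragment generation with metal adducts,
  disulfide-count variants and water losses; 20 ppm greedy one-to-one peak
  matching; interval logic that localizes each metal to the β- or α-domain.
* **Synthetic data** — seeded generators for every observable above, which
  is how the whole pipeline is validated without instrument files.

The human MT3 sequence (UniProt P25713), a pinned isotope table, and a
calibrant reference table are bundled under `inst/extdata/`.

## Worked example

Assign the stoichiometry of a simulated 5+ envelope of the Cu₄Zn₄ product,
then check its stability midpoint:

```r
library(metims)

mt3  <- mt3_sequence()                      # 68 residues, 20 Cys
sp   <- metal_complex(mt3, n_cu = 4, n_zn = 4, n_ss = 2)
obs  <- synth_spectrum(sp, charges = 5, noise_sd = 0.01, seed = 101)

res <- assign_species(obs, candidate_grid(), mt3, z = 5)
head(res[, 1:7], 3)
#>   n_cu n_zn n_ss     score     scale      mz_shift    residual
#> 1    4    4    2 0.9993340 0.9984012 -1.483609e-05 0.008870305
#> 2    6    2    1 0.9954282 0.9513811 -6.983233e-03 0.024010522
#> 3    7    1    1 0.9916941 0.9237358 -8.791380e-03 0.032727911

cv  <- synth_sy(e50 = 1.04, w = 0.08, noise_sd = 0.02, seed = 7)
fit_e50(cv)
#> <sigmoid fit> E50 = 1.0400 eV (se 0.0046), w = 0.0807 eV, top 0.987, bottom 0.033
```

The top-ranked candidate recovers the generating species — four Cu(I), four
Zn(II), two disulfides — with a score near 1 and a visible margin over
runner-up compositions whose masses differ by only ~2 Da (a Cu/Zn/disulfide
rearrangement at 5+ is a ~0.4 Th shift). The E50 fit recovers the
programmed 1.04 eV midpoint within the noise.

The `analysis/` directory holds the full narrative as numbered drivers —
`01_simulate_spectra.R` through `05_topdown_localization.R` — each a thin
script over the package functions that prints what it finds and writes its
tables under `results/`.

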