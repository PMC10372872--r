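---
title: "Methods: native IM-MS characterization of Cu(I)/Zn(II)-metallothionein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: native IM-MS characterization of Cu(I)/Zn(II)-metallothionein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metims)
```

# Scope and scientific setting

Metallothionein-3 (MT3) is a 68-residue, 20-cysteine brain protein that
buffers Zn(II) and scavenges Cu(II). When the fully reduced Zn7 complex
reacts with Cu(II), copper is reduced to Cu(I) with concomitant formation of
intramolecular disulfides, producing a ladder of Cu(I)x Zn(II)y species whose
dominant end point carries four Cu(I), four Zn(II) and two disulfides. Native
mass spectrometry can follow this chemistry species-by-species, but only if
three hard problems are solved computationally:

1. **Stoichiometry assignment.** Cu and Zn differ by just 1.8 Da in average
   mass, and a disulfide changes the mass by only 2 H. At 7 kDa the isotopic
   envelopes of candidate species overlap heavily, so assignment must be done
   by fitting complete simulated isotope patterns, not by centroid mass.
2. **Conformation.** Traveling-wave ion mobility reports drift times, not
   collision cross sections (CCS); a calibration against proteins of known
   CCS is required before conformer populations can be compared.
3. **Metal localization.** Top-down fragmentation of the intact complex
   yields b/y ions that may retain metals; mapping which fragments are
   metal-free localizes the metals to the N-terminal (beta) or C-terminal
   (alpha) domain.

This package implements that full pipeline and a synthetic-data generator
that emulates each observable, so every stage is testable end to end without
instrument data.

# The mass model

## Compositions and the hydrogen-displacement rule

A species is `metal_complex(base, n_cu, n_zn, n_ss)`. Its neutral elemental
composition is

    apo (fully reduced) + n_cu * Cu + n_zn * Zn - n_H * H,
    n_H = n_cu + 2 * n_zn + 2 * n_ss

Each Cu(I) displaces one thiol proton, each Zn(II) two, and each disulfide
removes two hydrogens. This charge-neutral bookkeeping reproduces the
observed chemistry: the transition from the Zn7 reduced complex
(`n_H = 14`) to the Cu4Zn4 product with two disulfides (`n_H = 16`)
changes the proton count by exactly the two hydrogens lost to disulfide
formation, i.e. metal swap occurs without net proton gain or loss. The rule
is implemented as a single function so an alternative displacement policy
can be substituted.

Two cysteine-derived budgets constrain admissible species (both
configurable, since bridging thiolate coordination is richer than the
budget's one-thiolate-per-metal floor): `n_cu + n_zn + 2 n_ss <= n_Cys` and
`n_H <= n_Cys` (every displaced proton is a thiol proton). On the default
candidate grid (Cu 0-8, Zn 0-7, SS 0-2) these budgets leave 196 species.

## Isotope patterns

`isotope_pattern()` convolves per-element isotopologue distributions
(binary-exponentiation self-convolution per element, then cross-element
convolution). Two numerical controls matter:

* `bin_width = 1e-4` Da: sticks closer than this merge into an
  abundance-weighted aggregate. This is far below both the instrument peak
  width at 7 kDa (a 20,000 resolving-power peak is ~0.35 Da FWHM) and the
  smallest fine-structure splittings that survive at that resolution.
* `prune = 1e-10` (absolute abundance per step): keeps the stick count
  bounded; retained total abundance stays above 0.999 (asserted in tests),
  and the pattern is renormalized to sum to one.

The simulator is validated against a brute-force oracle that enumerates
every per-atom isotope assignment for small (<= 10 atom) compositions;
agreement is at the 1e-12 abundance level when binning is refined to 1e-6 Da
so that no genuinely distinct isotopologues merge.

The isotope masses and abundances themselves are pinned in a packaged CSV
(IUPAC/CIAAW values for H, C, N, O, S, Cu, Zn) so results cannot drift with
external library updates. All m/z conversions use the proton mass
(1.007276 Da), never the hydrogen atom mass, and assume proton charging only
(native positive mode, no salt adducts).

## Profile rendering

Sticks become Gaussians with FWHM = m/z / resolving power and area equal to
stick abundance. The default resolving power of 20,000 is a documented
assumption of a Synapt-class quadrupole-TOF; it is a parameter everywhere.
Before rendering, sticks are merged at one fifth of the narrowest peak
sigma — a pure optimization whose effect on the profile is below 1e-6
relative (tested).

# Stoichiometry assignment

`assign_species()` scores every candidate on the grid against the observed
envelope and ranks by score. Scoring (`score_fit()`) uses the cosine
similarity between the rendered theoretical profile and the observed
intensities on the observed grid. Cosine was chosen over stick matching
because it is insensitive to centroiding conventions and to overall
intensity scale (score is exactly 1 iff the profiles are proportional); a
reduced-chi-square alternative is available via `method = "chisq"`.

Numerical choices:

* A bounded global m/z shift (default +/- 0.05 Th) is optimized to absorb
  calibration offset. The bound is deliberately smaller than the 0.2 Th
  isotopologue spacing of a 5+ ion so the optimizer cannot "hop" the pattern
  by one isotope peak and report a spurious fit.
* Ties are broken by parsimony — fewer total metals, then fewer disulfides —
  after quantizing scores at 1e-9 so floating-point noise cannot scramble
  the order.
* Candidates whose envelope does not overlap the observed window score `NA`
  and rank last; this is what makes an exhaustive grid search cheap, since
  only mass-compatible candidates are rendered.
* Charge, when unknown, is read from the reciprocal median spacing of
  resolved isotope peaks (`estimate_charge()`).

Overlapping multi-species spectra are decomposed by non-negative least
squares (`fit_mixture()`) over candidate profiles rendered on the observed
grid; because each basis profile has unit area per unit coefficient, the
NNLS coefficients normalize directly to molar-like fractions.

# Ion mobility: TW calibration and conformer analysis

The traveling-wave calibration follows the standard protein-calibrant
protocol: corrected time `t' = t - EDC * sqrt(m/z) / 1000`, reduced-mass and
charge-corrected reference `CCS' = CCS_ref * sqrt(mu) / z`, and a linear fit
of `ln CCS'` on `ln t'` giving the power law `CCS' = A t'^B`. The EDC delay
coefficient and the calibrant charge states are required inputs with no
silent defaults, because they are instrument settings. Calibrations carry an
optional TW parameter-set tag (e.g. wave velocity/height) and refuse to be
applied to arrival-time data tagged with a different set.

The bundled calibrant table (ubiquitin, cytochrome c, beta-lactoglobulin;
nitrogen values after the Bush laboratory compilation) ships with a version
stamp; its absolute accuracy does not affect any test, which all use
round-trip constructions.

Intensities are carried through the time-to-CCS transform unchanged (no
Jacobian correction), matching common practice for apex/FWHM reporting on
TW instruments; this is a reporting convention, not a density transform, and
is documented on `atd_to_ccs()`. Apex extraction smooths with a Gaussian of
2 grid steps by default (configurable to 0), breaks ties toward the lower
CCS, and reports FWHM by linear interpolation at half maximum; a delta-like
single-bin mode reports one grid step by convention.

CIU fingerprints normalize each collision-energy column to unit maximum
(the standard fingerprint convention; unit-area normalization is available).
The compact/extended boundary defaults to the intensity minimum between the
two largest modes of the CE-summed distribution, because the experimental
boundary between the ~1000 and ~1300 A^2 conformer families is not a
published constant; it is always overridable. Conformer fractions integrate
trapezoidally on either side of the boundary with the boundary bin split by
interpolation, so fractions are continuous in the boundary, sum to one
exactly, and are scale-invariant.

# Survival-yield stability analysis

Survival yield is `precursor / (precursor + products)`; what counts as a
"product" is a policy: by default metal-loss species count as dissociation
products, not survivors (switchable). Lab-frame energy `z * V_trap` is
normalized to the center-of-mass frame by `m_gas / (m_gas + m_ion)`.
Curves are fit with a four-parameter falling logistic,

    SY(E) = bottom + (top - bottom) / (1 + exp((E - e50) / w)),

by Levenberg-Marquardt with asymptotes bounded in [0, 1.2], the starting
midpoint at the energy whose SY is nearest 0.5 and starting width a quarter
of the span. Fits require at least 5 points spanning at least half the SY
dynamic range; a midpoint outside the sampled energies is not accepted.
Parameter-recovery simulations over midpoints {0.8, 0.95, 1.04, 1.2} eV at
2% SY noise (15 points, 20 replicates each) keep the E50 bias below 0.002
eV, an order of magnitude inside the 0.02 eV acceptance band.

# Top-down fragment annotation and metal localization

`generate_fragments()` enumerates b/y ions only (CID chemistry; electron
transfer dissociation of these complexes yields no fragments, so c/z ions
are left as an extension point of the type). Adduct states enumerate metal
counts and disulfide counts per fragment — disulfides by count, not
position, because positions are unobservable at this level — pruned by the
fragment's own cysteine budget. Matching is against monoisotopic m/z (for
these <= 4 kDa fragments the monoisotopic peak is within the tolerance of
the most abundant isotopologue; full-envelope verification can reuse the
isotope module). Peak assignment is greedy one-to-one by ascending absolute
ppm error with ties broken toward the chemically simpler adduct state.

Localization logic: a matched metal-free `y_k` testifies that the C-terminal
k residues can be metal-free, confining that metal to residues
`[1, L - k]`; b-ions give the mirrored prefix bound. Under partial
metalation both a metal-free and a metal-bearing copy of the same fragment
can coexist (two precursor populations), so the implementation is
conservative: a metal-bearing `y_j` with `j <= k` blocks the exclusion of
that suffix rather than being treated as an error. Evidence in which a
metal-bearing fragment sits strictly inside a longer matched metal-free
suffix is surfaced through an `inconsistent` flag, never silently. Two
domain-boundary conventions are supported: the 9-cysteine beta-domain ends
at residue 31 (default), or the alpha-domain is counted as the C-terminal
30 residues (boundary `L - 30` = 38 for MT3); the bundled analysis uses the
latter when interpreting the y30 ladder.

# The synthetic-data generator

Every generator is a pure function of its parameters and a mandatory seed
(whenever noise is requested), and its defaults are the study conditions the
analyses target:

* `synth_spectrum()`: isotopically resolved envelopes at 20,000 resolving
  power, 5+ (and 4+) charge states, Gaussian intensity noise at 1% of the
  maximum for the noisy condition.
* `synth_ciu()`: two conformers at 1000 and 1300 A^2 with a logistic
  compact-to-extended transition across the 0-60 V trap CE ramp.
* `synth_sy()`: sigmoid survival-yield curves; the two bundled midpoints
  are 0.95 eV (Zn7 reduced) and 1.04 eV (Cu4Zn4, two disulfides) with width
  0.08 eV and 2% noise.
* `synth_fragment_peaks()`: planted fragment peaks with ppm jitter plus
  decoys guaranteed >= 50 ppm from every theoretical ion (rejection
  sampling).

What the generator does **not** emulate — and therefore what passing tests
do not demonstrate about real data — includes: detector saturation and peak
tailing, chemical noise and background, charge-state-dependent transmission,
space-charge effects, conformer interconversion during the mobility
separation, and any systematic error in the bundled calibrant reference
values. Assignment accuracy on real spectra will degrade with resolution and
signal-to-noise in ways the 1%-Gaussian noise model only sketches.

# Problem sizes and determinism

The validation suite runs at desk scale by design: the exhaustive
assignment sweep covers all 196 grid species at 4+ and 5+ (392 noise-free
assignments); noisy-replicate checks use 20 replicates; E50 recovery uses
4 midpoints x 20 replicates; localization soundness uses 100 random
fixtures. Isotope patterns are memoized per composition within a session,
which is what makes the exhaustive sweep affordable. All stochastic tests
and the acceptance script derive their random streams from fixed or
user-supplied seeds, so reruns are bit-identical.

# Known limitations

* The hydrogen-displacement and budget rules are stoichiometric
  bookkeeping, not coordination chemistry; exotic bridging arrangements
  outside the budgets must be enabled explicitly.
* The mixture model decomposes a single charge state; full-spectrum,
  cross-charge deconvolution and absolute quantification are out of scope.
* CCS values are calibrated TW values, not first-principles (Mason-Schamp)
  cross sections; no CIU50 curve fitting is attempted beyond the conformer
  ratio trajectory.
* Fragment matching ignores internal fragments and probabilistic site
  localization; domain assignment is interval logic over b/y evidence.
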