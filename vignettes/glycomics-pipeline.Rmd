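---
title: "Methods: composition-level MALDI-TOF N-glycomics with glycotrait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition-level MALDI-TOF N-glycomics with glycotrait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotrait)
```

## The measurement model

glycotrait works at the *composition* level: an N-glycan is a count
vector (H, N, F, L, E) of hexoses, N-acetylhexosamines, deoxyhexoses
(fucoses), lactonized and ethyl-esterified N-acetylneuraminic acids. The
derivatization chemistry makes sialic acid linkage mass-visible — α2,6
NeuAc is esterified (+C₂H₄), α2,3 NeuAc lactonizes (−H₂O) — so L and E
counts act as linkage proxies. α2,8-linked NeuAc also lactonizes and is
therefore indistinguishable from α2,3 here; it is not modelled.

The ion observed in positive reflectron mode is the singly charged sodium
adduct. `composition_mass()` sums pinned residue monoisotopic masses plus
H₂O and Na and subtracts one electron mass; the electron convention
matters at the third decimal and matches the printed calibrant values to
better than 1 mDa (the worst case among the 19 calibrants, H9N8, differs
by 0.8 mDa, consistent with rounding of the printed value). Elemental
formulas drive isotopic envelopes: per element the n-atom distribution is
the single-atom isotope polynomial raised to the n-th power
(exponentiation by squaring on convolutions), then elements are convolved
together. Isotope abundances are IUPAC 2021 representative values pinned
in one table. Isotopologue spacing defaults to the average 1.00235 Da
rather than per-formula exact spacing — at the peak widths modelled here
the difference is far below the integration window.

## Spectrum processing

The processing chain mirrors standard targeted MALDI glycomics software:

* **Smoothing** — Savitzky–Golay, order 2, window = nearest odd point
  count spanning m/z 0.06 at the local sampling interval (floored at 5
  points so the quadratic fit is not an identity), applied 4 cycles.
  Total ion current is preserved to well under 1%.
* **Baseline** — tophat: the morphological opening with a flat
  structuring element (default 3 Da, much wider than a peak, much
  narrower than baseline structure) is subtracted. The running min/max
  uses the van Herk block algorithm, O(n) per pass.
* **Noise and peaks** — noise is 1.4826 × MAD of intensity in a sliding
  20 Da window, evaluated on a 5 Da grid and interpolated; peaks are
  local maxima with parabolic apex refinement, kept at S/N ≥ 3.
* **Recalibration** — known-composition peaks are matched to picked peaks
  within 100 ppm; only peaks with S/N ≥ 9 may serve as calibrants, which
  prevents calibrants that happen to be absent from a sample from
  latching onto noise peaks. A least-squares polynomial (degree ≤ 3) maps
  observed to theoretical m/z; matches whose residuals sit far outside
  the bulk (beyond 3 robust SDs, floored at 2 ppm) are dropped once and
  the fit repeated. Fewer than five matched calibrants is a hard error.
  On noiseless input distorted by a known cubic the recalibrated
  calibrant residuals are below 1 ppm (this is asserted in the test
  suite). The packaged default calibrant list is the 19 reference
  glycans; the simulation roundtrip calibrates against the full target
  list, since every analyte of known composition with a strong peak is a
  legitimate calibrant and individual species can be absent from any one
  sample.
* **Extraction** — for each target composition the first three
  isotopologues are integrated in ±2σ windows (σ defaults to 0.05 Da,
  matching reflectron resolution at these masses); truncating at three
  isotopes is the standard guard against overlap with heavier
  co-eluting envelopes. The summed area is divided by the first-three
  isotopic fraction and by the Gaussian window coverage (95.45% at 2σ) so
  that an isolated noiseless analyte is recovered at its full envelope
  area. The quality score (QS) is the mean absolute deviation between
  observed and theoretical first-three isotopologue fractions.
* **QC** — spectra pass when total analyte area exceeds 1×10⁵ and
  *strictly more than* half of the analyte area comes from analytes with
  S/N above 9; analytes pass when S/N > 6, |ppm error| < 20 and the QS
  criterion is met. All boundary comparisons are strict.

**The QS direction.** The criterion is conventionally printed as
"quality score > 0.10", yet a deviation score is better when smaller. The
default here interprets the intent — `qs ≤ 0.10` passes — and the printed
direction is available via `qs_direction = "above"` in `qc_analyte()`.

Technical replicates are combined by summing spectra on a shared m/z axis
before extraction (the combine-spectra order); extraction-level
combination can be composed manually from the building blocks if wanted.
Passing analyte areas are rescaled to a total relative intensity of 100%
per sample.

## Derived traits

All trait formulas live in `trait_registry()`. Whole-profile traits
(MultiFuc, MonoFuc, SialylTotal, HexNAcGeHex, HexNAcGe7, HighMannose) are
percentages of total abundance. Complex-type traits (CFa, CFc, CLFa,
Sia23, Sia26, GalPerAntenna, SiaPerGal) are abundance-weighted means over
the complex-type subset only — the within-class normalization is what
makes values like "galactosylation per antenna ≈ 80%" possible in
profiles dominated by high-mannose species, and it parallels the
fraction-of-complex definition of CFa. Per-antenna forms are the default
for the sialylation linkage traits; per-glycan variants can be registered
alongside without touching the pipeline.

Structural class follows the composition rule: N = 2 splits into
high-mannose (H ≥ 5) and paucimannose (H ≤ 4); N = 3 with H ≥ 5 is
hybrid; everything else is complex. For complex species antennae = N − 2
(floored at 1) and galactoses = min(H − 3, antennae) floored at 0. Two
caveats are intrinsic to composition-level data: a bisecting GlcNAc is
indistinguishable from an extra antenna (the rule counts it as one), and
undergalactosylated antennae can only occur in compositions with
HexNAc ≥ Hex, which couples GalPerAntenna and HexNAcGeHex (see below).
Empty denominator subsets yield `NA`, never 0.

## The synthetic cohort generator

The generator emulates a 16-cell-line, two-group design: 8 samples with
high and 8 with low expression of the transcription factor CDX1, 3
technical replicates each. The trait presets
(`reference_trait_targets()`) encode the reported group contrast —
multi-fucosylation 54% vs 33%, overall sialylation 21% vs 36%, α2,3
sialylation per antenna 11% vs 23%, galactosylation per antenna 72% vs
85%, HexNAc≥7 27% vs 20%. Where only a direction was reported the means
were chosen once: α2,6 sialylation 12% vs 18% (so that sialylation per
galactose lands near 31% vs 48%), HexNAc≥Hex 25% vs 12% (a >2-fold
increase, placed high enough that the galactosylation targets remain
jointly feasible), and high-mannose 35% vs 45% (no absolute value is
reported; with a high-mannose share above ~45% a whole-profile
multi-fucosylation of 54% would be arithmetically impossible, so the
generator uses a moderately high-mannose-dominated profile, higher in the
low group in line with the mesenchymal phenotype of those lines). The
between-sample spread is 8 percentage points for every trait, a free
parameter of the generator — the source data show boxplots only.

Per-sample trait values are drawn around the group means with the
structural couplings respected *by construction*: high-mannose,
galactosylation, per-antenna sialylation, multi-fucosylation and
HexNAc≥7 are drawn freely (clipped to their feasible ranges), while
overall sialylation and HexNAc≥Hex are drawn as their structural floor —
(Sia23+Sia26)·complex-share and (1−GalPerAntenna)·complex-share
respectively — plus a non-negative excess whose moments are set so the
marginal group means still match the targets. A residual joint
feasibility check rejects and redraws rare violations. This keeps
realized group means close to the presets instead of inheriting heavy
truncation bias.

Abundances are then allocated over a curated library of 74 compositions
(the H5–9N2 high-mannose series, minor paucimannose/hybrid species, and
complex species spanning 0–4 fucoses, 0–2 L, 0–2 E, HexNAc-rich and
highly branched variants). Each drawn trait vector induces a set of
linear constraints on the abundance vector; a ridge-regularized
non-negative least-squares solve anchored at a random Dirichlet start,
polished by cyclic projections onto the constraint hyperplanes (clipping
at zero), yields a profile whose computed traits match the drawn values
to ~1e-6 percentage points — comfortably inside the 1-point allocation
tolerance the generator promises. The library is deliberately curated so
that no two envelopes collide in three-isotope extraction: all pairwise
monoisotopic gaps below 4.5 Da stay at least 0.22 Da away from every
multiple of the isotopologue spacing. This removes, for example, the
classic Hex+HexNAc+lactone vs two-ethyl-ester near-isobar (0.036 Da
apart). Real cell-line peak lists are larger (~221 species) and *do*
contain such overlaps; the roundtrip results here therefore quantify
pipeline correctness, not the envelope-deconvolution problem, which the
three-isotope truncation only mitigates.

Spectra are rendered on a 1000–5000 m/z axis (0.01 Da sampling) as
Gaussian isotopologue peaks (σ = 0.05 Da, five isotopologues per
analyte), a smooth exponentially decaying baseline, additive Gaussian
noise, and a cubic miscalibration polynomial producing shifts of a few
tens of ppm — inside the 100 ppm initial match window of recalibration.
Replicates share the sample's miscalibration (one target-plate
calibration) and differ in noise. What is *not* simulated: detector
saturation and dead time, matrix cluster ions, isotope-resolved peak
shape asymmetry, mass-dependent resolution, and chemical noise that
correlates across m/z. Passing roundtrip tests therefore show the
processing chain inverts the rendering model faithfully; they do not
certify performance on vendor raw data.

The expression module draws a log2 matrix for a configurable glyco-gene
panel (fucosyltransferases, branching and elongation enzymes,
sialyltransferases, HNF1A/HNF4A, LGALS4, CDX2) with group shifts encoding
the reported directions (e.g. GMDS log2 shift 1.888 ≈ 3.7-fold, LGALS4
4.52 ≈ 23-fold, ST3GAL6 down) and per-gene noise SD 0.5. CDX1 itself is
drawn from a two-group lognormal whose moments come from the packaged
per-line reference values, so the simulated high/low ratio of arithmetic
means scatters around the 65-fold reference ratio.

## Statistical layer

Group contrasts of traits use the two-sided Mann–Whitney test —
`stats::wilcox.test`, exact for group sizes up to 10 without ties, normal
approximation with tie correction otherwise — with Bonferroni correction
over the family of emitted traits (13 by default; the family size is
reported alongside the p-values). At n = 8 + 8 the attained size of the
exact test at α = 0.05 is 0.0499. Differential expression uses Welch
t-tests by default (pooled variance by flag) with Bonferroni over the
tested gene subset and fold change 2^(Δ mean log2). Trait–gene
association is ordinary least squares per pair. PCA is `prcomp` on
mean-centred, unit-variance-scaled profiles (constant compositions
dropped), with component signs fixed so the largest-magnitude loading is
positive; plain explained variance is reported — no cross-validated
component selection is attempted.

## Problem sizes and runtimes

The test suite and the acceptance script run the full roundtrip at the
study scale (8 + 8 samples × 3 replicates, 74-species library, 400k-point
spectra), the detection-rate loop over 100 simulated cohorts through the
generator + trait + test layer (rendering is exercised by the roundtrip;
repeating it 100× would add nothing but wall time), and the null-size
estimate over 1000 cohorts drawn at the trait layer, where the test under
study operates. These sizes were chosen as the smallest that pin each
quantity to its Monte-Carlo precision.

## Known limitations

* Composition-level identification cannot separate structural isomers:
  bisecting GlcNAc vs antenna, LacdiNAc vs bisection, type-1 vs type-2
  chains, α2,8 vs α2,3 sialylation.
* The galactosylation/HexNAc≥Hex coupling means those two traits cannot
  be varied independently; the generator honours the coupling, and real
  profiles are subject to the same arithmetic.
* No envelope deconvolution: overlapping species beyond the three-isotope
  guard bias each other, as they do in the emulated software.
* The synthetic library (74 species) is smaller than real cell-line peak
  lists; `glycan_library(extra = ...)` extends it, but extensions are not
  collision-checked automatically.
* Trait spread, baseline shape and noise levels are generator choices,
  not measured properties of any instrument.
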