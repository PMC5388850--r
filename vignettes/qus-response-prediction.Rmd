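---
title: "Methods: quantitative ultrasound features for a-priori response prediction"
author: "qusresponse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative ultrasound features for a-priori response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qusresponse)
```

## The problem

Only a minority of locally advanced breast cancer (LABC) patients achieve a
complete pathological response to neoadjuvant chemotherapy, and response is
normally known only months into treatment. Quantitative ultrasound (QUS)
examines the frequency content of the raw radiofrequency (RF) backscatter
signal — information discarded by conventional B-mode imaging — and can probe
tissue microstructure at the cell-cluster scale. This package implements a
complete a-priori prediction pipeline: spectral and backscatter-model
parameters are estimated over a tumour core region and a surrounding margin
ring from pre-treatment RF data, summarized into per-patient texture and
image-quality features, fed to classifiers under leave-one-patient-out
cross-validation (LOOCV), and linked to recurrence-free survival (RFS).

Because no clinical RF archive is publicly deposited for this problem, the
package ships a physically motivated RF simulator and cohort generators, so
every stage is exercised end-to-end on synthetic data with known ground
truth.

## Acoustic model

**Normalized spectra.** Each region of interest is tiled into 2 x 2 mm
analysis blocks with 80% adjacent overlap (step 0.4 mm). Per block, Hann
windowed periodograms of the scan-line segments are averaged and divided by
the laterally averaged spectrum of a reference phantom at the same depth:
`S(f) = 10 log10(P_sample / P_reference)` dB. The division cancels the
system transfer function and diffraction, which is why two simulations with
different pulses but identical tissue agree on `S(f)` to within a fraction
of a dB (a property test asserts < 1 dB).

**Linear fit (MBF, SS, SI).** A least-squares line over the usable band
(default: the -6 dB band of the pulse, 4.2-7.8 MHz for the 6 MHz probe)
gives the spectral slope SS (dB/MHz), the 0-MHz intercept SI (dB) and the
midband fit MBF (dB), with the exact identity `MBF = SS * f_c + SI` at the
band centre `f_c`.

**Backscatter model (ASD, AAC).** The Gaussian form-factor model in dB is

```
M(f) = AAC + 10 log10(f^4) + 10 log10(exp(-0.827 k^2 a_eff^2)),  k = 2 pi f / c
```

(Insana-Hall constant 0.827). The effective scatterer diameter is
`ASD = 2 a_eff`; AAC is the effective acoustic concentration, reported in dB
relative to the reference phantom because absolute system calibration
constants are unavailable. The fit is a deterministic coarse grid over
`a_eff` in [1, 150] um (the dB offset AAC is closed-form for each candidate)
followed by golden-section refinement between the neighbouring grid points;
a solution at the grid boundary is flagged. Because AAC is a pure offset,
spectral gain separates exactly: adding 3 dB to a spectrum moves AAC by 3 dB
and leaves ASD untouched.

**Attenuation (ACE).** The spectral difference method regresses the dB
sample/reference ratio against depth at each frequency, then regresses those
slopes against frequency. The package uses the convention that the
round-trip power from depth `z` (cm) is reduced by `4 * alpha * f * z` dB
with `alpha` in dB/cm/MHz (the dB form of the classical `exp(-4 alpha z)`
power law), so the slope-of-slopes is `-4 (alpha - alpha_ref)` and
`ACE = alpha_ref - slope / 4`. The same factor appears in the point
compensation `S(f) += 4 (ACE - alpha_ref) f z`, making
correct-after-attenuate an exact inverse — asserted to 1e-12 in tests. ACE
is a single value per core ROI (no parametric image), and the compensation
path is measured from the shallowest core row, reflecting that only the
tumour is assumed to differ from reference-like overlying tissue.

## The RF simulator

The simulator is the package's test substrate, not a diffraction-accurate
acoustic model:

* **Phantoms** are uniform random point-scatterer fields with ground-truth
  `a_eff`, acoustic concentration (dB) and attenuation slope. The count is
  `round(density * area)`; a fixed seed reproduces positions exactly.
* **Beam model.** Each scan line accepts scatterers within half a pitch
  laterally, weighted by a Gaussian profile (sigma = pitch/4) — the simplest
  model producing realistic speckle statistics.
* **Synthesis is in the frequency domain.** Each scatterer contributes
  `A(f) exp(-i 2 pi f (2z/c))`, with `A(f)` the product of the Gaussian
  pulse spectrum, `f^2 sqrt(FF(f))` (the amplitude form of the `f^4` x
  form-factor power model) and the per-scatterer cumulative attenuation
  `10^(-4 alpha f z / 20)`. This makes attenuation exact per scatterer —
  simpler and more accurate than segment-wise time-domain overlap-add, which
  is why that alternative was not used. Echo delays are continuous (no
  sample quantization), so a scatterer at 20 mm peaks exactly at sample
  `round(2 * 0.020 / 1540 * 40e6) = 1039` (0-based).
* **Speckle statistics.** With many scatterers per resolution cell the
  envelope is Rayleigh and mean/sd approaches 1.913 from below; with the
  narrow beam model, about 400 scatterers/mm^2 are needed to get within 5%.
* **The reference phantom** uses point (Rayleigh, `a_eff = 0`) scatterers,
  0 dB concentration and 0.5 dB/cm/MHz — stand-ins exposed as configuration,
  since the physical phantom's properties are a free choice. Where a
  strongly averaged reference is needed (attenuation recovery studies), a
  wide frame (128 lines) mimics the many independent lateral positions a
  physical phantom scan provides.

A spectrum-level oracle (`synthesize_block_spectrum()`) evaluates the
backscatter model directly on a frequency grid; the RF route and the oracle
agree on mean normalized spectra to well within the 3 dB tolerance asserted
in tests (measured: < 1 dB).

## Regions, textures and features

The margin ring is built from an exact Euclidean distance transform computed
in physical millimetres (anisotropic pixels supported — RF pixels are
~0.02 x 0.25 mm), so a thickness of "5 mm" means 5 mm in tissue, not in
pixels. Blocks are tiled on a lattice anchored at the mask bounding box;
a block is kept when at least half its pixels are inside the mask
(`min_inside = 0.5`, configurable — a compromise between coverage and
core/margin contamination), and a block satisfying both masks is assigned to
the core. Per-parameter block values form parametric images on the block
lattice.

Textures are Haralick features (contrast, correlation, energy, homogeneity)
of a gray-level co-occurrence matrix computed on the parametric image (the
native resolution of the estimates): min-max quantization to G = 16 levels,
distance-1 offsets in four directions pooled into one symmetric GLCM.
Pooling (rather than averaging per-offset features) was chosen as the more
stable variant for the small images involved; both G and the offsets are
configuration. Min-max quantization makes the texture vector invariant to
affine rescaling of the parameter. A constant region cannot be quantized
and yields the degenerate limits CON = 0, ENE = 1, HOM = 1 with correlation
recorded as missing.

Two image-quality features compare core and margin populations of each
parametric image: `CMR = mean_core / mean_margin` (SNR-style) and
`CMCR = |mean_core - mean_margin| / sqrt(sd_core^2 + sd_margin^2)`
(CNR-style, scale-invariant but deliberately not shift-invariant). These are
the standard SNR/CNR analogues; both are isolated behind small functions so
alternative definitions can be swapped without touching callers.

The full per-patient grid is `{MBF, SS, SI, ASD, AAC} x {core, margin} x
{MEAN, CON, COR, ENE, HOM}` plus `{param}_CMR`, `{param}_CMCR` and
`ACE_core_MEAN`: 61 features, averaged unweighted across the 4-7 image
planes covering the tumour (a feature is missing only if missing in every
plane). ER/PR/HER2 markers can be appended as 0/1 columns.

## Classification

* **Ranking.** Per feature, a Shapiro-Wilk check (alpha = 0.05, per class)
  gates between an unpaired t-test and a Mann-Whitney test, one-tailed in
  the direction of the observed class-mean difference (the direction is not
  fixed a priori; under the null the doubled p-values are uniform, which is
  what the null-cohort test asserts). Features are sorted ascending by p.
* **Forward selection.** Starting from the lowest-p feature, candidates are
  added in rank order and kept only on a strict LOOCV-accuracy improvement;
  ties keep the smaller model. By default selection is run once on the whole
  dataset (the classical wrapper protocol); a fully honest mode re-runs
  ranking + selection inside every outer fold at a substantial cost.
* **Classifiers.** Fisher's linear discriminant (via `MASS::lda`), an
  RBF-kernel soft-margin SVM (via `e1071::svm`; C and gamma tuned on a
  log2 grid, defaults `2^-5..2^15` and `2^-15..2^3` in steps of 4x, by
  inner LOOCV on the training fold), and a weighted k-NN with posterior
  `P(C_j | x) = sum_{i in nbd, i in C_j} W_i / sum_{i in nbd} W_i`,
  `W_i = 1/(d_i + eps)`, `eps = 1e-8` guarding zero distances; k is chosen
  over odd values up to 15 by inner LOOCV. SVM scores are mapped through a
  logistic link on the decision value, which preserves the ranking used for
  AUC. All standardization (z-scores) and tuning happen inside each
  training fold.
* **Metrics.** Sensitivity, specificity and accuracy in percent with a
  configurable positive class (good responders, or complete responders in
  the alternative grouping); AUC by the rank (Mann-Whitney) formula with a
  95% CI from 1000 patient-resampled bootstrap replicates (degenerate
  single-class resamples are redrawn); and a normality-gated two-sample test
  on the per-patient posteriors as a group-separation check.

A note on the null: LOOCV with label permutation is slightly pessimistic
(the held-out patient's class is under-represented in its training fold), so
permuted-label AUC centres near 0.45 rather than 0.50 at n = 56 — the
leakage-guard tests use averaged permutations and a band that accounts for
this.

## Survival

Kaplan-Meier curves use the product-limit estimator and log-rank tests the
standard 1-df chi-square, both via the survival package, with events
resolved before censorings at tied times. `stratify_by_prediction()`
replaces the true grouping with the classifier's predicted labels matched by
patient id and recomputes curves and test — the Fig-4-style analysis. The
log-rank p is cross-checked against a label-permutation null in tests.

## What the generators emulate — and what they do not

The synthetic study conditions are fixed once:

* **Cohorts**: 56 patients, 42 good / 14 poor responders (the clinical class
  split). The "separable" acceptance cohort uses six features each with a
  3-sigma class-mean shift — an idealized optimal feature set comparable in
  size to the nine-feature clinical one. A single 3-sigma feature alone has
  a Bayes accuracy of ~94.5% at these priors, so near-perfect accuracy is
  only a fair demand of a multi-feature cohort.
* **Survival**: exponential event times with hazards 0.002/month (good) and
  0.02/month (poor) — about 89% vs 30% five-year RFS — with independent
  exponential censoring at an expected 20% rate.
* **Pipeline demo**: 10 patients x 3 planes, 16 x 12 mm frames, 48 lines at
  0.25 mm pitch, a 4 mm-radius core disc, 30 scatterers/mm^2, classes
  separated in attenuation (0.9 vs 0.6 dB/cm/MHz), scatterer radius (30 vs
  55 um) and concentration (0 vs 4 dB). These sizes keep a full double run
  comfortably on one CPU while leaving every stage non-trivial.

Passing on this substrate demonstrates internal correctness — estimator
identities, oracle agreement, leakage-free cross-validation, deterministic
reports — not clinical performance. Real tumours are heterogeneous,
anisotropically attenuating, subject to diffraction and phase aberration,
and segmented by hand; none of that variability is modelled, and the
simulator's beam model is deliberately simple (no elevational dimension, no
focusing).

## Numerical choices and degenerate inputs

* Form-factor grid 1-150 um in 2 um steps + local refinement: deterministic,
  immune to local minima; edge solutions flagged but returned.
* Block spectra: Hann window, one-sided periodograms in the Parseval
  convention, zero-padded to 256 points.
* The distance transform uses the separable lower-envelope algorithm on
  squared distances with a finite sentinel (1e15) so envelope intersections
  stay finite after division by small squared pixel sizes.
* Degenerate cases have defined, tested behaviour: empty phantoms give
  all-zero frames; masks smaller than a block give empty tilings with a
  warning (not an error); constant regions give the degenerate texture
  limits; single-class training folds fall back to majority prediction with
  a warning; zero margin means make CMR missing.
* All generators take explicit seeds and restore the caller's RNG state;
  pipeline sub-seeds are derived arithmetically from the run seed, keeping
  everything below 2^31.

## Limitations

Manual segmentation sensitivity (margin thickness changes results), the
under-specified clinical reference phantom, and the absence of diffraction
compensation beyond reference division are inherited from the study design.
The honest per-fold selection mode exists precisely because whole-dataset
feature selection (the default, matching classical practice) optimistically
biases LOOCV estimates; on real data the honest mode is the defensible
choice.
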