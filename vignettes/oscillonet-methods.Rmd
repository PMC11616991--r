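---
title: "Methods: spectral parameterisation, dominance mapping, and network-molecular correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral parameterisation, dominance mapping, and network-molecular correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscillonet)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and why their defaults are what they
are, what the synthetic generators do and do not emulate, and the design
choices made where the design was genuinely open.

## 1. The spectral model

A channel's power spectrum is modelled, in log10 power, as an aperiodic
1/f-like background plus Gaussian oscillatory peaks:

$$\log_{10} P(f) \;=\; b - \chi \log_{10} f \;+\;
  \sum_i a_i \exp\!\left\{-\frac{(f-c_i)^2}{2 w_i^2}\right\}.$$

The background has offset $b$ (log10 power at 1 Hz) and exponent $\chi$
(unitless; steeper spectra have larger $\chi$). Each peak has a center
$c_i$ in Hz, a height $a_i$ in log10-power units *above the background*
(the "pw" parameter used for all downstream ranking), and a width $w_i$ in
Hz (Gaussian SD). The knee-free background form is used throughout: over
the fitted 1–100 Hz range a single power-law regime is assumed, and no
knee parameter is exposed. This is an assumption, not a finding — spectra
with a genuine knee inside the fitted range will absorb the bend into a
compromise exponent.

### Fitting stages

`spectral_fit()` estimates the model in stages:

1. **Peak-resistant aperiodic fit.** An ordinary least-squares line in
   log–log space is refit using only the bins lying at or below it, so
   bins elevated by peaks cannot drag the slope. On a pure power law this
   is exact; under a large peak the exponent error stays below 0.05.
2. **Iterative peak detection.** The flattened spectrum (observed minus
   background) is scanned for its maximum; if it exceeds
   `peak_threshold_sd` (default 2) standard deviations of the current
   flattened spectrum — and an absolute floor of $10^{-6}$ log10-power
   units that guards against machine-precision residual structure — a
   Gaussian is seeded there with a half-height width estimate, subtracted,
   and the scan repeats.
3. **Joint Gaussian refinement** by bounded Levenberg–Marquardt
   (`minpack.lm::nls.lm`), with centers confined to ±2 SD of their guess
   and widths clipped to the admissible range. Gaussians whose 0.75-SD
   bands overlap are pruned (the taller survives) and the fit repeated:
   without this, subtraction artefacts split one true peak into several.
4. **Aperiodic refit** on the peak-removed spectrum, then a **final joint
   polish** of all parameters together. The polish is what takes noiseless
   recovery from "good" to machine precision; on noisy data it is a
   standard full-model refinement.

`fit_error` is the mean absolute log10 residual of the final model, and
the reconstruction identity `fitted = aperiodic + periodic` holds exactly.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `peak_width_limits` | [0.5, 12] | Hz on $2w$ | admissible oscillation widths; the limits apply to twice the Gaussian SD, following the reference convention of the parameterisation method |
| `peak_threshold_sd` | 2 | SD of flattened spectrum | detection threshold |
| `min_peak_height` | 0 | log10 power | no absolute height floor |
| `max_n_peaks` | Inf | — | unbounded peak count |
| frequency grid | 1–100 Hz, 0.5 Hz steps | Hz | linear grid covering theta–gamma, finer than the narrowest admissible peak |
| Morlet `n_cycles` | 7 | cycles | fixed-Q wavelets; SD in time $= n_c/(2\pi f)$ |

A consequence of `min_peak_height = 0` with an unbounded peak count is
that noisy spectra legitimately acquire noise-scale peaks: with ~200
spectral bins the expected maximum of Gaussian noise is ≈2.6 SD, above the
2 SD threshold. These extras are harmless downstream — every analysis uses
the per-band *maximum* peak — and the test suite asserts they stay at
noise scale rather than pretending they do not occur.

### Morlet spectra

`morlet_psd()` convolves the signal with complex Morlet wavelets and
averages squared magnitude over time, excluding samples within half the
wavelet support of either edge. Wavelets are amplitude (L1) normalised, so
a unit-amplitude sinusoid yields power 1/4 at its own frequency at *any*
frequency — equal-amplitude components are recovered with equal power,
which matters when peak heights are compared across bands. Zero-padded
gaps between recording fragments are deleted beforehand
(`remove_zero_runs()`); channels left with under 10 s of signal should be
flagged and skipped by the caller, and the function's `min_samples`
argument errors with the channel name for that purpose.

## 2. Dominant-rhythm classification

Bands default to half-open intervals theta [4, 8), alpha [8, 13), beta
[13, 30), gamma [30, 100). Two conventions for the beta band are in
common use (13–30 and 13–35 Hz); the default follows the 13–30
classification convention, and `band_scheme("wide_beta")` selects the
13–35 variant, in which beta and gamma overlap on [30, 35) and a peak
there is eligible for both. The 12–13 Hz gap between the conventional
alpha and beta edges is folded into alpha, so the default scheme
partitions 4–100 Hz without gaps.

Peak heights are z-scored sequentially within electrodes, then subjects,
then the whole dataset (population SD; degenerate groups are centred
only). Whether the three stated levels were meant sequentially or as
alternatives is ambiguous; sequential application was chosen, and the test
suite asserts the property that makes the ambiguity harmless: each stage
applies one increasing affine map to all of a channel's peaks, so the
within-channel argmax — the dominant band — is invariant to the choice.
Ties break toward the lower-frequency band, then the lower center
frequency, for determinism. Channels with no fitted peak are reported as
having no dominant rhythm, never dropped silently.

Region assignment projects MNI coordinates into a labelled parcellation
volume; an unlabelled containing voxel falls back to the nearest labelled
voxel center within 5 mm, else "unlabelled". Hemispheres derive from the
sign of x with a ±2 mm midline strip. Hemispheric asymmetry of a band is
tested with a 2×2 chi-square without continuity correction (midline
excluded).

## 3. Network mapping

Channel seeds are binary spheres (default r = 5 mm: a voxel is set iff its
center lies within the radius), smoothed with a Gaussian kernel of 8 mm SD.
Smoothing is separable and edge-renormalised (divided by the smoothed
all-ones image), so constant images pass through unchanged while interior
intensity is conserved; SD in mm is converted per axis from the affine.

Functional maps correlate the seed-mean time series with every in-brain
voxel per subject, Fisher z-transform the correlations (|r| capped at
0.999999 so the transform stays finite), and average z across subjects —
the variance-stabilising convention standard in normative-connectome
mapping.
Grey-matter masking follows smoothing, and the order matters; the pipeline
fixes smooth → mask and a test pins the two orders apart. Whether r or z
maps are averaged is an open convention; z-before-averaging was chosen
for variance stabilisation.

Structural maps select streamlines with at least one vertex within the
seed radius (point-based, the cheap tract-density convention;
segment–sphere intersection is available by flag) and count each selected
streamline once per traversed voxel, sampling segments at half-voxel
steps. Group aggregation is the voxel-wise *mean* for functional maps
(missing-aware) and the voxel-wise *sum* for structural maps — streamline
counts are additive across seeds, and the test suite asserts exact
conservation.

## 4. Group contrasts with FWE control

Voxel-wise contrasts use the classical pooled-variance two-sample t
(not Welch), matching the two-group design-matrix formulation and
supporting unequal group sizes; zero-pooled-variance voxels are flagged
missing. The primary multiplicity control is **permutation max-T**: the
null distribution of the maximum t over voxels is built from group-label
relabellings — enumerated exhaustively when at most 10,000 relabellings
exist, otherwise from `n_perm` random draws plus the observed labelling —
and a voxel is significant when the fraction of null maxima at or above
its t is ≤ α. Parametric random-field FWE (the SPM convention) is the
common alternative in voxel-wise mapping; permutation was chosen as the
primary method because it is assumption-light and desk-verifiable against
exhaustive enumeration, with Bonferroni provided as a deterministic
cross-check that is never less conservative. Under the
null, the family-wise rejection rate at α = 0.05 calibrates to ≈0.05
(checked over 200 replicate synthetic datasets).

## 5. Molecular comparison

PET maps are resliced (trilinear) to a common grid, z-scored across
in-brain voxels, and averaged. "Spatial normalisation" before averaging is
implemented as this across-voxel intensity standardisation: the maps are
already in MNI space, and raw tracer units are not comparable across
radioligands, so averaging unstandardised maps would be meaningless.

The compound parcellation combines atlases by claiming voxels in
precedence order (first listed wins; regions fully shadowed are dropped
and the realised region count is data-dependent, not asserted). The
recommended precedence puts small subcortical structures before cortical
sheets so they are not swallowed. Each region carries the compartment of
its source atlas (cortex / basal ganglia / cerebellum).

Spatial similarity is Spearman's rho between compartment-restricted parcel
profiles, with a two-sided permutation p: parcels are permuted without
restriction (no spatial-autocorrelation-preserving null; a
variogram-preserving null would be a principled extension but is out of
scope) and $p = (1 + \#\{|\rho_\pi| \ge |\rho|\})/(1 + n_{perm})$.
With the default 9999 permutations the attainable floor is exactly
$10^{-4}$. Reports cross all maps × tracers × compartments and add a
Benjamini–Hochberg column.

## 6. What the generators emulate — and what they do not

The synthetic module generates every input with known ground truth:

* **Spectra / time series**: the exact generating model above, plus
  Gaussian log10-power noise; time series are white noise shaped in the
  frequency domain to the target PSD (direct spectral control, rather than
  AR processes). Generated signals are periodic by construction.
* **Cohorts**: dominant-band counts are one multinomial draw (defaults are
  the exact observed fractions 277/397/1005/93 of 1772 channels, which sum
  to 1 where the rounded percentages 15.6/22.4/56.6/5.2 do not); each
  channel's true
  band carries the strictly largest peak, secondary peaks are ≥ 2 widths +
  2 Hz away and at most 70% of the dominant height, so a correct
  classifier recovers truth exactly on noiseless spectra. Coordinates are
  drawn from Gaussian blobs at plausible lobe locations; electrode shafts
  group ~8 channels; the ECoG/sEEG mix matches the 258/1514 source ratio.
* **Connectomes**: voxels sharing a latent network share a subject-level
  latent signal mixed to a designed within-network correlation;
  cross-network correlation is 0 in expectation.
* **Tractograms**: polyline bundles rigidly jittered per streamline.
* **PET maps**: a parcel profile rank-normalised and mixed with noise at
  Pearson level $r = 2\sin(\pi\rho_s/6)$ — the bivariate-normal inversion
  of the Spearman–Pearson relation — so the realised Spearman correlation
  concentrates on the requested target.

Not emulated: volume conduction and reference montage effects, head
models, BOLD haemodynamics, spatial autocorrelation of real brain maps,
scanner noise, inter-subject anatomical variability, and the epilepsy
screening of real channels. Passing tests therefore demonstrate
correctness of the *computations* under the stated models, not robustness
to every artefact of real recordings.

## 7. Numerical choices and degenerate inputs

* Coordinates are MNI mm throughout the API; voxel indices are 0-based
  internally; the NIfTI affine is the single source of truth.
* The peak-detection absolute floor ($10^{-6}$ log10 units) exists only to
  reject machine-precision residual structure on noiseless input.
* Correlations of zero-variance voxels are set to 0 before Fisher
  averaging; |r| is capped at 0.999999.
* Degenerate z-scoring groups are centred only; constant profiles and
  constant PET maps are errors where a correlation or standardisation is
  undefined, and degenerate compartment pairs in a report become NA rows
  rather than aborting the run.
* All generators take an explicit integer seed and restore the caller's
  RNG state; identical seeds give bit-identical output.
* Problem sizes used by the test-suite calibrations — 200 spectra for
  recovery, a 1772-channel cohort, 200 null replicates of 20+20 maps on
  1000 voxels with 500 permutations, 200 parcels for correlation
  recovery — were chosen to make Monte-Carlo error small relative to the
  asserted bounds while keeping the default suite fast on one CPU.

## 8. Known limitations

Beyond the generator gaps above: the aperiodic model has no knee mode; the
permutation null is unrestricted (exchangeability across parcels/labels is
assumed); the pooled-variance t assumes equal group variances; trilinear
reslicing is not flux-conserving for strongly anisotropic downsampling;
and the winner-takes-all dominance logic is, by design, a simplification —
a channel contributes to exactly one rhythm's network even when it shows
multiple credible peaks.
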