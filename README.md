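# oscillonet

From invasive-EEG rhythms to whole-brain networks and molecular maps.

Resting intracranial EEG shows oscillatory peaks riding on a 1/f-like
background. Which canonical rhythm (theta, alpha, beta, gamma) dominates a
recording site, which whole-brain network those sites share, and how that
network overlaps with neurotransmitter systems are three questions that span
electrophysiology, MRI connectomics and molecular (PET) imaging.
`oscillonet` implements that full analysis chain for R users working with
channel-level iEEG, normative connectomes and PET uptake maps — together
with synthetic-data generators that make every stage testable end to end
with known ground truth, no downloads required.

## The model at the core

Each channel's Morlet-wavelet power spectrum (7-cycle complex wavelets,
time-averaged power) is parameterised as an aperiodic background plus
Gaussian oscillatory peaks, in log10 power:

    log10 P(f) = b − χ·log10 f + Σᵢ aᵢ · exp( −(f − cᵢ)² / (2 wᵢ²) )

with offset *b*, aperiodic exponent *χ*, and peaks of center *cᵢ* (Hz),
height *aᵢ* (log10 power above background, the "pw" parameter) and width
*wᵢ* (Hz). Fitting is staged: a peak-resistant aperiodic fit, iterative
peak detection against a 2-SD threshold of the flattened spectrum, joint
Gaussian refinement, an aperiodic refit on the peak-removed spectrum, and a
final joint polish. Peak widths are constrained so 2·w ∈ [0.5, 12] Hz, the
peak count is unbounded and the minimum height is 0.

Downstream, per-band maximum peak heights (z-scored within electrodes,
subjects and the dataset) give each channel a winner-takes-all **dominant
rhythm**; channel coordinates seed spherical ROIs (r = 5 mm, 8 mm-SD
Gaussian smoothing) whose **functional** (Fisher-z-averaged seed
correlations, grey-matter masked) and **structural** (streamline-count)
connectivity maps are aggregated per rhythm and contrasted voxel-wise with
pooled-variance t-tests under **permutation max-T family-wise error
control** (chosen over SPM-style parametric random-field correction
because it is assumption-light and exactly verifiable against exhaustive
enumeration; Bonferroni is included as a deterministic cross-check); and
the unthresholded group maps are compared to PET uptake maps
by **Spearman correlation of parcel profiles** (cortex / basal ganglia /
cerebellum compartments of a compound parcellation) with unrestricted
permutation p-values.

## Worked example

Fit one synthetic spectrum and classify a small cohort:

```r
library(oscillonet)

truth <- spectrum_truth(offset = 1, exponent = 1.2,
                        peaks = data.frame(center = c(9, 21),
                                           height = c(0.35, 0.6),
                                           width  = c(1.5, 2)),
                        noise_sd = 0.03, seed = 42)
fit <- spectral_fit(gen_spectrum(truth))
fit
#> Spectral parameterisation (aperiodic + Gaussian peaks)
#>   range: 1-100 Hz (199 bins)
#>   aperiodic: offset = 1.0342, exponent = 1.2205
#>   peaks: 6;  fit error (mean |log10 resid|): 0.0211
```

The two generating peaks are recovered at 8.7 Hz (height 0.31) and 21.1 Hz
(height 0.58); the remaining entries are noise-scale bumps (height ≤ 0.13)
that the unbounded-peak-count convention admits on noisy input — the
per-band *maximum* peak, which drives everything downstream, is unaffected.

```r
cohort <- gen_cohort(cohort_truth(n_channels = 300), seed = 1)
fits <- lapply(cohort$truths, function(tr) spectral_fit(gen_spectrum(tr)))
names(fits) <- cohort$channels$channel_id
dom <- classify_dominance(fits, cohort$channels)
table(dom$dominant_band)
#> alpha  beta gamma theta
#>    60   168    23    49
tabulate_dominance(dom, "true_lobe")[, 1:8]
#>   true_lobe n_channels theta_n theta_pct alpha_n alpha_pct beta_n beta_pct
#> 1 Cingulate         47       5     10.64       7     14.89     30    63.83
#> 2   Frontal         76      13     17.11      13     17.11     40    52.63
#> ...
hemisphere_test(dom, "beta")$p_value
#> [1] 0.755
```

On this noiseless cohort the classification matches the generator's truth
for every channel; beta dominates (168/300 = 56%), mirroring the dominance
fractions the generator draws from. `run_demo(seed = 1)` chains all five
stages — spectra, dominance, seed-based network maps, the beta-vs-alpha
t-map with permutation FWE thresholding, and the compartment-wise PET
correlation report — on synthetic data in about a minute.

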