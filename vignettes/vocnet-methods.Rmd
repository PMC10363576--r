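---
title: "Methods: ensemble decoding of a vocal repertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble decoding of a vocal repertoire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`vocnet` analyses how small ensembles of auditory neurons encode a
categorical vocal repertoire — concretely, the 10 behaviorally defined
call types of the zebra finch ethogram (Be, LT, Th, Di, Ag, Wh, Ne, Te,
DC, So).  The pipeline has six stages: acoustic featurization, neural
featurization, Gaussian naive-Bayes ensemble decoding, modulation
receptive fields (MRFs) in a call-type discriminant space, clustering
comparisons via the adjusted Rand index, and ensemble-corrected
inference.  Every stage runs end to end on a built-in synthetic-data
generator with known ground truth, which is what the test suite
exercises.

# Acoustic representation

**Spectrogram.** A short-time Fourier transform with Gaussian tapers of
50 Hz frequency-domain SD (equivalently 3.18 ms in time; total window
6 SD ≈ 19 ms) and a 1 ms hop, band-limited at 10 kHz.  Amplitudes are
normalized to the spectrogram maximum so that playback level does not
leak into downstream representations, converted to dB and floored 80 dB
below the maximum.  The floor bounds the log range before the Fourier
analysis of the spectrogram; it is configurable.

**Modulation power spectrum (MPS).** The 2D Fourier power of the log
spectrogram, computed in 100 ms Gaussian-tapered segments (SD 16.7 ms)
shifted by 33 ms within the first 500 ms of the stimulus and averaged.
The redundant half-plane is folded so the spectral-modulation axis
(cycles/kHz) is nonnegative and the temporal-modulation axis (Hz) is
signed.  Two numerical choices are ours: each segment's mean log
amplitude is removed before the transform (the DC term otherwise
dominates every comparison), and waveforms are zero-padded to the 500 ms
analysis window before the spectrogram so that calls shorter than one
segment — several call types last ~100 ms — contribute the same number
of full segments, analyzed in their natural silence context.  Partial
segments are never used.  The default grid derives from the native FFT
sizes (106 spectral × 101 temporal bins); `mps_paper_grid()` is a
documented zero-padding preset that reproduces a 103 × 192 = 19,776-
dimensional grid.  The exact padding behind that published bin count is
not stated anywhere we could verify, so the preset pins the counts
without asserting equivalence of the axis calibration.

**Bioacoustic features.** Twenty named features: temporal-envelope
moments (meanT, stdT, skewT, kurtT, entropyT, rms, maxAmp) computed by
treating the 50 Hz-low-passed analytic-signal envelope as a distribution
over time; spectral-envelope moments and cumulative quartiles (meanS,
stdS, skewS, kurtS, entropyS, Q1–Q3) from the normalized periodogram;
and pitch features (saliency, meanF0, maxF0, minF0, cvF0) from
framewise normalized autocorrelation (25 ms frames, search band
80–1500 Hz).  Saliency is the mean height of the autocorrelation peak;
frames below 0.5 are unvoiced and fully unvoiced stimuli get missing F0
statistics, mean-imputed before clustering.  Autocorrelation is the
minimal faithful pitch tracker for this purpose and is isolated behind
one interface so a different tracker can be substituted.

# Neural featurization

**Response strength (Z).** Per trial, the spike count in the 500 ms
after onset minus the count in the 500 ms before, z-scored per unit
across all trials and stimuli.  We use the population (1/n) SD — the
choice is not documented in the field's convention for this metric —
because it makes two identities exact: mean(Z) = 0 and SD(Z) = 1 per
unit, and the within-call-type noise metric evaluates to exactly 1 when
all vocalizations are pooled into one group.  Both identities are
asserted in the tests.

**Temporal principal components (T1–T5).** PSTHs are kernel-density
estimates (Gaussian, 30 ms SD) on a 1 ms grid over 0–500 ms, with
kernel-mass renormalization at the window edges so the curve integral
equals the mean spike count.  One PCA is fitted per dataset across all
(unit, stimulus) rows with at least 5 trials; single trials are
projected by binning the spike train on the same grid, subtracting the
PCA centering vector, and taking inner products with the components.
Using the fit's own centering vector keeps single-trial coefficients
unbiased around the row scores.

**Selectivity and noise.** The rate-based selectivity index is
SI = (1 − mean(z_CT)² / mean(z_CT²)) / (1 − 1/n) over per-call-type mean
response strengths; 0 for uniform tuning, 1 for one active class.
Because the class means are signed z-scores, the formula can exceed 1
when excitatory and suppressed responses cancel; such values are
reported raw with a flag, mirroring how the entropy selectivity's
domain edge is handled.  The
entropy selectivity GS = 1 − Hobs/Hmax is computed from the diagonal of
a unit's decoder confusion matrix; the printed formula can fall below 0
when the diagonal terms are individually high-entropy, and such values
are reported raw with a flag rather than clamped.  Within-call-type
noise is the population SD of Z within each call type, averaged over
call types.

# Decoding

A Gaussian naive-Bayes classifier over per-trial features (Z only, or
Z + T1–T5 per unit): class-conditional feature means and variances plus
empirical class priors, evaluated in log space.  A variance smoothing of
1e-9 × (largest feature variance) guards singular likelihoods.
Cross-validation holds out one exemplar stimulus per call type (all of
its trials); the confusion-matrix row of the true class accumulates the
*averaged posteriors* of the test trials (soft confusion), and PCC is
the mean diagonal × 100.  Posteriors are averaged over test trials
within an ensemble and then across ensembles when ensembles are pooled;
the alternative pooling order is not distinguishable from the published
description, so ours is documented here.  Ensembles of size 1 and 2 are
enumerated exhaustively; larger sizes are sampled as distinct random
subsets.  Because selecting the top fraction of noisy scores is biased
upward, `refit_top_fraction()` re-scores the top ensembles with an
independently drawn held-out exemplar and reports the refreshed values.

# MRFs, discriminant space, volume

Each unit's tuning is summarized by six MRFs: response-weighted averages
(1/N) Σ w_s ΔMPS_s with weights w ∈ {Z, T1..T5}, trial-averaged per
stimulus, where ΔMPS is the stimulus MPS minus the mean MPS over the
set.  Weights are used raw and the average is divided by the stimulus
count; no whitening by the stimulus autocovariance is applied, so MRFs
are spike-triggered-average-like objects living in the same space as
the MPS.

The call-type discriminant space solves the generalized eigenproblem of
the between-class covariance (covariance of call-type mean MPS) against
the within-class covariance (average per-type covariance).  The ambient
dimensionality (~10⁴–2×10⁴) far exceeds the stimulus count (~110), so
the within matrix is singular; we first reduce to the principal
components capturing 99% of the stimulus-set variance (further capped
so the within matrix stays nonsingular), solve there with a 1e-8 ridge,
Gram–Schmidt-orthonormalize the leading axes, and map them back.  This
is deterministic and faithful to the between/within eigenvector
construction on the identifiable subspace; it is a reconstruction, not
a verified replica of the original regularization.

The volume spanned by an ensemble is the determinant of the 3×3
covariance of its 6k projected MRF coordinates (k units × 6 components).
Tiny negative determinants from floating point are clipped to zero.
Decoder performance is regressed on volume (bivariate) and on
{volume, mean noise, mean SI, mean GS} (full model), with inference
delegated to the corrected statistics below.

# Clustering comparisons

Acoustic clustering standardizes the 20 features per column (they have
heterogeneous units), optionally applies a caller-supplied nonlinear
embedding function (the contract under which a UMAP-style algorithm can
be plugged in; the default path is embedding-free and fully
deterministic), and runs hierarchical agglomeration with Ward linkage —
the linkage method is not documented for the original analysis, and
Ward is surfaced as a default, not hidden.  Neural clustering uses the
stimulus × 6k trial-averaged feature matrix per ensemble.  Every cut of
a dendrogram is scored by the adjusted Rand index against the call-type
labels (ARI_call) or the acoustic cluster labels (ARI_acoustic); the
best cut takes the smallest k on ties, and the degenerate
both-partitions-trivial case is reported as 0 with a flag.

# Ensemble-corrected inference

Ensembles of ne units drawn from a fixed pool of ns share units, so
treating n sampled ensembles as independent grossly understates
uncertainty.  The corrected machinery is: corrected variance
sc² = ns/(ns−ne) × snc², effective sample size neff = ns − ne + 1,
SEM = sc/√neff, F = (neff/n)·((SSt−SSe)/(k−1))/se² on (k−1, neff−k)
degrees of freedom, paired t on neff−1, two-sample t on
neff₁ + neff₂ − 2, and the usual adjusted R² as effect size.  With
ns = 100 and ne = 20, these give the dfs 76/79/80/160 used throughout
the analysis.  t p-values are two-sided and F upper-tailed (sidedness
is a documented default).  A calibration simulation in the tests shows
what the correction buys: for inference about the underlying neuron
population, the naive SEM's 95% intervals cover at only a few percent
while the corrected intervals are an order of magnitude wider and
several-fold better calibrated.  The correction remains anticonservative
for a pure mean statistic in that simulation — a property of the printed
construction, reported as measured rather than idealized.

# The synthetic generator

The generator defines the study conditions the package is tested under.

**Stimuli.** Each call type is a parametric spec: a harmonic stack at a
sampled F0 mixed with band-limited noise (mixing weight = pitch
saliency), a Gaussian formant-band emphasis, an AM envelope, and
sampled duration and level; 10 types × 11 renditions reproduce a
110-stimulus playback set.  The per-type defaults are qualitative
reconstructions of the zebra finch repertoire (tonal Te/DC/LT around
550–800 Hz, noisy Be with a formant band above 4 kHz, Ag near 2 kHz,
long modulated Di, soft Ne, short Th, long heterogeneous So); the
quantitative per-type distributions are not published, so these values
were chosen once to reproduce the described qualitative contrasts —
e.g. a Te-like call concentrates spectral-modulation power just below
2 cycles/kHz — and are not revisited.  Song is synthesized as a single
heterogeneous syllable string; no syrinx modeling is attempted.

**Units.** A unit is a rectified linear–nonlinear model on the MPS:
rate(t) = baseline + gain · max(0, drive) · profile(t) · g, with drive
the standardized inner product of a ground-truth template with the
stimulus ΔMPS, profile an onset/sustained mixture over 0–500 ms, and g
a lognormal trial gain (SD = `noise_sd`).  Spikes are inhomogeneous
Poisson in 1 ms bins over [−0.5 s, duration + 0.5 s]; the 500 ms
pre-stimulus window carries baseline-only spiking so Z is computable
exactly as defined.  Templates are mixtures of a preferred call type's
mean ΔMPS and a smoothed random filter (`purity` sets the mix), giving
heterogeneous but call-type-informative tuning.  Ground truth (templates
and drives) is serialized next to the data so recovery tests never
re-derive it.

**Calibration.** The default signal/noise regime (gain 2–7 Hz,
noise_sd 1.2, purity 0.4) was calibrated so that single-unit decoding
sits at the published operating point for this preparation — unit
PCC_Z+T near 12% against a 10% chance level, with ensemble performance
rising into the tens of percent by 20 units.  This matters beyond
realism: leave-one-exemplar cross-validation under label shuffling is
*below* chance for implausibly clean units, because the held-out
stimulus's true-type siblings occupy 10 of the 109 remaining slots of
its own shuffled class versus 11 for every other class, and sharp
posteriors amplify that deficit.  At the realistic operating point the
posterior softness restores the 10% chance level, which is the regime
the decoder's null-calibration checks run in.

**What the generator does not emulate.** Noise correlations between
units (trial gains are independent), non-Poisson spiking statistics
(bursting, refractoriness), response adaptation across trials, and
acoustic recording artifacts.  Passing tests therefore certify the
pipeline's correctness and its behavior under a realistic
signal-to-noise regime, not the biological claims themselves on real
recordings.

# Problem sizes and determinism

Tests run on scaled-down designs chosen as the smallest sizes where
each property is statistically resolvable: most module tests use 50
stimuli × 12 units × 6 trials; parameter-recovery and decoder-property
tests use the full 110-stimulus design with 20 units; the chance-level
check uses 100 units × 110 stimuli × 10 trials with 60 ensembles of 20.
Every stochastic stage takes an explicit seed and a fixed seed
reproduces stimuli, spike tables and all downstream numbers exactly
(asserted in the tests).  Degenerate inputs are handled explicitly:
zero-SD units are flagged and dropped, all-zero selectivity is NA with
a warning, singleton call-type groups are skipped, ARI of two trivial
partitions is 0 with a flag, and sub-identifiable regressions are
refused (or, for the optional full model in the pipeline, skipped with
a warning).

# Known limitations

* The MPS grid preset pins published bin counts but not an axis-by-axis
  calibration of the original analysis grid.
* The discriminant-space regularization (PCA reduction + ridge) is one
  defensible choice in the rank-deficient regime, not a verified
  replica.
* The auditory-unit screen (any call type with |mean Z| significant at
  p < 0.01) is a reconstruction of a criterion defined in prior
  literature.
* The corrected inference implements the printed formulas exactly; its
  calibration for mean statistics is improved but not nominal (see the
  calibration test), and no permutation/bootstrap alternative is
  provided.
* Real-data ingestion is limited to the plain tabular formats; no
  raw-electrophysiology parsing or spike sorting is included.
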