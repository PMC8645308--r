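---
title: "Methods: summary texture statistics and the texturality classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary texture statistics and the texturality classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texturality)
```

## The model

The package asks an operational question from visual psychophysics: given a
grayscale image, will the human visual system treat it as a *texture* — a
region adequately represented by a fixed set of global summary statistics —
or as a structured, non-texture image (an object, a scene)?  The working
hypothesis is that texturality is predictable from the image's own
Portilla–Simoncelli (PS) statistic set: images whose perceptual content
survives summary-statistic encoding are statistically homogeneous, and that
homogeneity is visible in the statistics themselves.

The pipeline has four stages:

1. **Decomposition.** A complex steerable pyramid with $N = 4$ dyadic
   scales and $K = 4$ orientations (the standard PS parameterization, with
   a $7 \times 7$ autocorrelation neighborhood).
2. **PS statistics.** Marginal moments, central autocorrelations,
   and cross-orientation / cross-scale correlations of the linear
   (real-part) and energy (magnitude) subbands — some 1,300 scalars.
3. **Summary variables.** Within-class, within-frequency averages that
   collapse the set to 34 labeled variables, e.g. `cpE@16` = cross-position
   energy correlation at 16 cycles per image (cpi).
4. **Screening and classification.** Logistic correlations of each variable
   with behavioral response proportions; an RBF-kernel SVM on the top-6
   (or the 12 moment-only) variables, evaluated by stratified 10-fold
   cross-validation.

## Pyramid construction

The decomposition is built entirely in the frequency domain with
polar-separable masks: a raised-cosine radial profile with one-octave
transitions and an angular profile $\cos^{K-1}(\theta - \theta_k)$,
$\theta_k = (k-1)\pi/K$, with orientation 1 centered on the horizontal
frequency axis (a vertically oriented filter).  The complex ("analytic")
bands keep only one half-plane per orientation at doubled amplitude, so the
magnitude of a band is a local energy envelope and its real part is the
even-symmetric oriented band.  Design choices that matter:

* **Circular boundary handling.**  All filtering uses the DFT, so circular
  shifts of the input shift every subband exactly — tested at $10^{-8}$ —
  and the reconstruction identity is exact to floating point.
* **Downsampling by frequency cropping.**  Alias-free and exactly
  invertible; the amplitude convention (no renormalization on cropping)
  follows the original construction, so coarse-band variances grow by a
  factor of 16 per scale.  All correlation-class features are unaffected;
  the `power` features are monotone re-scalings per band.
* **Mean removal.**  The image mean is removed before decomposition and
  carried separately; PS marginal statistics handle it explicitly.
* **Default size 256 px.**  At the stimulus geometry the method was
  developed for (4.1 deg at 0.97 min/pixel, about 254 px) 256 is the
  nearest dyadic size; any square size divisible by $2^N$ with a coarsest
  level at least 7 px works.

## Statistic conventions

* Moments are population moments (divide by $N$); kurtosis is non-excess,
  so Gaussian maps read 3.  Zero-variance maps report skewness 0, kurtosis
  3, and identity/zero correlation matrices — a blank image flows through
  the whole pipeline without special-casing.  This degenerate branch is
  constructed, not measured: numerically-zero subbands of a constant image
  would otherwise correlate their own rounding noise.
* Autocorrelations are circular, normalized by the map's variance (center
  entry 1); the unnormalized variance travels separately as the `power`
  class.  The FFT implementation is tested against a direct
  spatial-domain sum at $10^{-10}$.
* Band magnitudes are mean-subtracted before correlation; cross-scale
  statistics correlate a scale's bands with the *phase-doubled* upsampled
  bands of the next coarser scale.  Phase doubling
  ($b \mapsto |b|e^{2i\arg b}$, applied after frequency-domain zero-pad
  upsampling) makes coarse-band phase progression commensurate with the
  finer scale; it never changes magnitudes, which the tests exploit as an
  independent oracle.
* Cross-band statistics are Pearson correlations.  The linear cross-scale
  block correlates real parts against both real and imaginary parts of the
  phase-doubled parents (a $K \times 2K$ matrix).

## The 34-variable summary layout

The published method names the summary classes and their total (34, with a
12-variable moment-only subset) but does not enumerate the layout.  The
layout used here is the only decomposition we found consistent with every
printed count and every named selected feature:

| class | meaning | per |
|---|---|---|
| `power` | orientation-averaged band-coefficient variance | band (64/32/16/8 cpi) |
| `skew`, `kurt` | moments of the partial lowpass image | band |
| `cpL` | mean off-center autocorrelation, partial lowpass | band |
| `cpE` | mean off-center autocorrelation, band magnitudes | band |
| `coL`, `coE` | mean off-diagonal cross-orientation correlation (real / magnitude) | band |
| `cfE` | mean adjacent-scale magnitude correlation | pair (labeled 32/16/8 cpi) |
| `cfL` | mean **absolute** adjacent-scale linear correlation | pair |

$7 \times 4 + 2 \times 3 = 34$; the moment classes give exactly
$3 \times 4 = 12$.  Cross-scale pairs are labeled by the coarser band
because the selected features are reported at 8 cpi, which exists only as
the coarser member of a pair.  `cfL` averages absolute values because the
signed real/imaginary cross-scale terms cancel under the phase convention;
all other classes average signed values.

## Logistic correlation

"Logistic correlation" is defined here (the source leaves it open) as:
standardize the feature $x$, fit the two-parameter logistic
$\hat p = \mathrm{logit}^{-1}(a + bz)$ by binomial maximum likelihood,
treating each per-image proportion as the mean of `n_trials` binary
responses, and report $\mathrm{sign}(b)\,\mathrm{cor}(\hat p, p)$.  The
definition lives behind a single function so it can be swapped.  A feature
that separates the two response levels perfectly drives the deviance to
zero before the coefficient path converges; that is treated as a perfect
fit, not a failure.

## Classifier

The kernel is Gaussian RBF, $K(x, z) = \exp(-\|x - z\|^2 / s^2)$, applied
to z-scored features (training-fold statistics only).  Standardization is
implied by the magnitude of the published kernel scales (0.0015–1.7): raw
feature scales differ by orders of magnitude across classes.  No SVM
solver ships in the supported environment, so the C-SVC dual is solved
in-package by sequential minimal optimization with maximal-violating-pair
selection (stopping tolerance $10^{-5}$ on the KKT gap); the test suite
checks it against an independent box-constrained dual maximizer and
closed-form/separable cases.  Proportions exactly at the 0.5 labeling
threshold are excluded and reported, since "higher or lower than 0.5"
leaves equality undefined.  Fold assignment is stratified and seeded;
models persist as JSON with 17-significant-digit numbers, which
round-trips doubles exactly.  The four published (box constraint, kernel
scale) pairs ship as named presets, with **no** attached accuracy claim:
the 500-image behavioral dataset they were tuned on is not distributed.

## The synthetic world

The original image set and judgments are unavailable, so the package
carries generators built around the causal claim under test: texture
generators are realizations of stationary processes (1/f^α noise, dense
Gabor fields, binarized noise, Poisson dot fields), non-texture generators
impose global position-dependent structure (a single large blob, a horizon
scene with hard-edged foreground objects, a large outlined polygon, a
mirror-symmetric layout).  A simulated observer turns summary features
into response proportions through the same logistic-binomial structure the
screening analysis assumes.

Parameter choices, made once: noise exponents default to α = 1 (the
natural-image slope); the Gabor carrier is 8 px (32 cpi at 256 px, the
middle of the pyramid's range) at ~0.004 elements/px²; dot fields use
σ = 2.5 px blobs at ~0.003/px²; the observer default is unit weight on one
feature, decision noise SD 0.5, 32 trials/image.  The scene generator uses
five hard-edged objects so that scenes carry broad-spectrum, low-frequency
structure; the blob is placed within ±15% of center so left/right halves
differ; binarized noise uses α = 1 so its grain stays fine relative to a
half-image crop.  The last three choices keep the generators true to
their stated roles — textures statistically homogeneous at half-image
scale, non-textures globally structured — which the stationarity-gap test
quantifies (texture half-image feature distances below half the
non-texture level).

What a green test does **not** establish: nothing about photorealism,
about the categories of real photographic stimuli, or about reproducing
the published human correlations (r ≈ 0.9) and accuracies (88–93%) — those
require the undistributed behavioral data.  Mirror-symmetric non-textures
are a deliberate hard case: their left/right summary features are equal by
symmetry, so the class gap rests on the other generators.

## A calibration fact worth knowing

Adjacent orientation filters of the $\cos^{K-1}$ bank are not orthogonal:
45°-apart profiles have a full-plane inner product of
$(9\cos\frac{\pi}{4} + \cos\frac{3\pi}{4})/10 \approx 0.566$.  White noise
therefore shows a *deterministic* cross-orientation correlation
(≈ 0.57 for real parts, ≈ 0.30 for magnitudes) and a positive
cross-position energy baseline (≈ 0.19), not a zero-centered null.  The
test suite freezes these Monte-Carlo-calibrated baselines; a white-noise
"null" of ±0.05 holds only for the `cpL` and `cfL` classes.  One
acceptance clause that asserts the idealized < 0.05 cross-orientation null
is accordingly left failing by design, with this analysis as its record.

## Known limitations

Luminance-only (color images are converted by Rec.709 weights before
analysis); square dyadic sizes only; no texture synthesis; behavioral
reproduction out of scope.  Images travel as NetPBM PGM/PPM or CSV — the
supported environment has no PNG/TIFF codec, and 16-bit PGM is lossless to
1/65535 for this purpose.
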