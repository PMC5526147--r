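---
title: "Methods: BIF-histogram segmentation of phase-contrast images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BIF-histogram segmentation of phase-contrast images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifseg)
```

## The model

`bifseg` treats segmentation of phase-contrast microscopy (PCM) images
as per-pixel texture classification. The pipeline has three stages.

**Local structure (BIFs).** The image is filtered with a bank of
derivative-of-Gaussian kernels up to second order at scale
$\sigma_B$. Responses are scale-normalised,
$s_{ij} = \sigma_B^{\,i+j}\,(I * G^{(ij)}_{\sigma_B})$, so that the
same structure detected at different scales yields comparable
magnitudes. From the second-order responses we form the Laplacian
$\lambda = s_{20} + s_{02}$ and the directional-variance term
$\gamma = \sqrt{(s_{20}-s_{02})^2 + 4 s_{11}^2}$ (the difference of
the Hessian eigenvalues, always $\ge |s_{20}-s_{02}| \ge 0$). Seven
competing measures — flat $\varepsilon\,|s_{00}|$, slope
$2\sqrt{s_{10}^2+s_{01}^2}$, dark blob $+\lambda$, bright blob
$-\lambda$, dark line $(\gamma+\lambda)/\sqrt2$, bright line
$(\gamma-\lambda)/\sqrt2$, saddle $\gamma$ — are evaluated per pixel
and the largest wins. The classification is invariant to positive
intensity scaling (every measure is 1-homogeneous in the image) and
equivariant under rotations and flips; negating the image swaps the
dark/bright classes and leaves flat, slope and saddle fixed.

**Locally orderless pooling.** A pixel's BIF label alone is a weak,
noisy descriptor. The informative signal in PCM is the local *mixture*
of structure classes: cytoplasm yields a characteristic blend of
blobs, lines and saddles, background is mostly flat/slope. We
therefore build soft-edged local histograms: each class-indicator mask
is filtered with a unit-sum Gaussian window of standard deviation
$\sigma_w = w/2$ for a nominal window diameter $w$, and the per-pixel
histogram is the vector of filtered indicators. Because the kernel
sums to one, the masks partition the image, and boundaries are handled
by reflection, histograms sum to exactly one everywhere.

**Classification.** Histograms are concatenated across scales (and
optionally across intensity and contrast channels) and fed to a
random forest. A strict majority of tree votes labels a pixel
foreground; the raw vote map is the final segmentation, with no
morphological clean-up, so every reported score reflects the
classifier alone.

## Parameters that matter

* `scales` (px): the $\sigma_B$ progression, default `c(1, 2, 4)`.
  Small scales capture granularity, larger scales capture
  colony-level structure; doubling steps follow scale-space
  convention, and combinations beyond three scales mostly add runtime.
* `window` $w$ (px, odd or even integer $\ge 1$): the histogram
  support, the key tuning knob. Texture with fine, dense detail is
  separable with small windows; sparse or monolithic texture needs
  windows comparable to the spacing of its distinguishing features.
  `w = 1` degenerates to a single raw label per scale and serves as
  the baseline showing what pooling buys.
* `epsilon` (dimensionless, default 0.03): the flatness threshold,
  the fraction of mean local intensity below which gradients and
  curvatures are considered noise. It interacts with the
  $\lambda$-convention (below); 0.03 works across scales for
  intensity-scaled images.
* Forest: `n_trees = 20` (gains beyond that are marginal for pixel
  classification and cost linearly in time), `mtry = ⌊√F⌋`, fully
  grown trees, `n_samples = 50000` training pixels by default.

## Numerical choices

* **Kernels** are sampled Gaussians truncated at radius
  $\lceil 4\sigma_B\rceil$ (truncation error $<10^{-4}$) and
  moment-corrected: derivative kernels are adjusted to annihilate
  constants exactly and to return exactly 1 and 2 on a unit ramp and
  on $x^2$ respectively. Without this correction, sampling error at
  $\sigma_B \le 2$ is of order $10^{-3}$ and shows up as spurious
  blob/line responses on smooth gradients.
* **Boundaries** use symmetric reflection everywhere, which keeps the
  histogram unit-sum exact at image borders.
* **Window truncation**: the paper-style "kernel width equal to $w$"
  clips a $\sigma_w = w/2$ Gaussian at one standard deviation.
  Default truncation is instead at radius $2\sigma_w = w$
  (≥95% of the Gaussian mass), renormalised; the literal
  one-sigma clip is available as `truncation = "half_window"`.
* **$\lambda$ convention**: classical BIF papers use
  $\lambda = s_{20}+s_{02}$; reading "mean over directions" literally
  would halve it and shift the flat/blob balance at fixed
  $\varepsilon$. Default is the sum convention (under which
  $\varepsilon = 0.03$ was calibrated); `lambda_convention = "mean"`
  switches.
* **Flatness measure**: implemented as
  $\varepsilon\,|s_{00}|$ rather than $\varepsilon\,s_{00}$. For real
  (non-negative) images the two coincide; the magnitude form keeps
  the polarity-swap symmetry exact on arbitrary-signed inputs.
* **Ties** in the seven-way argmax go to the lowest class code
  (flat > slope > … > saddle), making output deterministic; ties of
  an even tree vote go to background (conservative foreground calls).
* **Degenerate inputs**: a constant image quantises to intensity bin
  0 and has zero contrast everywhere; the contrast filter
  (soft-windowed coefficient of variation, std/mean) offsets its
  denominator by machine epsilon times the largest local mean so it
  never divides by zero. The exact formula of the original contrast
  filter is in a prior paper we do not reproduce; the coefficient of
  variation is the standard reading of "normalised contrast" and is
  swappable behind the channel interface.
* **Intensity quantisation** uses the per-image min–max range
  (PCM illumination varies between fields of view), quantising after
  blurring; building a 256-bin histogram first and aggregating to 10
  bins would differ only in bin-edge placement.
* **`w = 1` baseline** encodes the per-scale label as a single
  numeric column. Trees split such categorical codes by thresholds,
  which is acceptable for the 7-way BIF alphabet but is a documented
  approximation.

## The synthetic data generator

Real PCM datasets with dense expert ground truth are not publicly
available for this task, so the package generates its own study
material. `generate_pcm_image()` emulates the statistical structure
that makes PCM segmentation hard:

* **shade-off**: object interiors at `shade_off` (default 0.95) times
  the background level, so mean intensity is nearly uninformative;
* **halo**: an additive bright rim (amplitude 25, decay width 4 px)
  just outside each object boundary — halos are artefacts and are
  *excluded* from the foreground mask, so a learner must label them
  background;
* **illumination gradient**: a smooth random-orientation plane
  (amplitude 10 on a background of 100);
* **textures**: fine-grained background noise (sd 3, grain 1 px)
  versus coarser, stronger interior granularity (sd 10, grain 2 px),
  the organelle-scale texture cue that real PCM foregrounds carry.

Objects are harmonically perturbed discs (three colonies of radius
14–26 px per 128×128 field), placed without overlap; masks are the
exact object support, so there is no annotation noise.

`generate_cocultured_image()` emulates a colony/feeder co-culture on a
256×256 field: one large monolithic region (class A) whose interior is
quiet except for sparse ±25 granules (about one per 17×17 px), a
surrounding band of fine elongated streaks (class B), and background
elsewhere, with class means matched to well under 2% of the dynamic
range. The sparseness of class-A structure is deliberate: a small
histogram window frequently contains no granule and then resembles
background, so reliable discrimination requires windows comparable to
the granule spacing — reproducing the qualitative window-size effect
that monolithic cell types demand large windows while intricate
textures are captured by small ones.

What the generator does *not* emulate: physically based Zernike
phase-contrast optics, annotation noise and inter-annotator
disagreement, debris and out-of-focus material, vignetting, or cell
crowding with touching objects. Scores on the synthetic suites
therefore demonstrate that the implementation learns and localises
texture under shade-off and halo conditions; they are not predictions
of F-scores on any particular real dataset.

## Study sizes

The shipped evaluation suites use 10 images of 128×128 px (binary
task, LOOCV with 5,000 sampled pixels per round) and 6 images of
256×256 px (co-culture task). These sizes give stable LOOCV means
(per-image sd ≈ 0.02–0.05) while keeping a full run in tens of
seconds on one core; they are the package's chosen study conditions
and all reported numbers are computed at these sizes by
`scripts/acceptance.R` and the test suite.

```{r example, eval = FALSE}
ds  <- generate_pcm_dataset(synthetic_spec(), 10, seed = 1)
cfg <- feature_config(scales = c(1, 2, 4), window = 15)
loocv(ds$images, ds$truths, cfg, n_trees = 20, n_samples = 5000,
      seed = 2)
```

## Known limitations

* Only axis-aligned second-order structure enters the feature set;
  the oriented 23-class BIF extension is out of scope.
* One window size per model: combining several $w$ simultaneously is
  not supported.
* The multi-class co-culture task is handled one-vs-rest (the target
  class against everything), not as a true 3-class classifier.
* Colour input, automatic scale selection and probability calibration
  are out of scope; the forest's majority vote is used raw.
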