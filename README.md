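# bifseg

Trainable pixel-wise segmentation of phase-contrast microscopy (PCM)
images using local histograms of Basic Image Features (BIFs) and a
random forest.

## The problem

PCM is the workhorse label-free imaging mode for live cell culture, but
its contrast mechanism produces two artefacts that defeat intensity
thresholding: **shade-off** (object interiors are nearly as bright as
the background) and bright **halos** hugging object boundaries. What
does distinguish cells from background is local *texture* — the
granular structure of cytoplasm versus the flat, finely noisy
background. `bifseg` segments PCM images by learning that texture from
annotated examples, for tasks such as foreground/background separation
of stem-cell colonies or discriminating two cell types in co-culture.

## The method

1. **BIF classification.** At each scale σ_B, the image is filtered
   with derivative-of-Gaussian kernels up to second order and each
   response is scale-normalised, s_ij = σ_B^(i+j) (I ∗ G^(ij)_σ).
   With λ = s20 + s02 (Laplacian) and
   γ = √((s20 − s02)² + 4 s11²) (directional variance), each pixel is
   assigned the class of the largest of seven measures:

   | class | measure |
   |---|---|
   | flat | ε·\|s00\| |
   | slope | 2·√(s10² + s01²) |
   | dark blob | +λ |
   | bright blob | −λ |
   | dark line | (γ + λ)/√2 |
   | bright line | (γ − λ)/√2 |
   | saddle | γ |

   with flatness threshold ε = 0.03.

2. **Soft local histograms.** For each class, its binary indicator
   mask is filtered with a normalised Gaussian window of standard
   deviation σ_w = w/2 (window diameter w). The per-pixel 7-bin
   histogram sums to one by construction and encodes the texture
   statistics of the pixel's neighbourhood while discarding the
   arrangement inside it (a locally orderless representation).

3. **Classification.** Histograms are concatenated across scales
   (optionally with 10-bin blurred-intensity and normalised-contrast
   histograms), giving M×7 features for M scales. A random forest
   (20 trees, ⌊√F⌋ candidate features per split) is trained on pixels
   sampled from annotated images; a strict majority vote labels each
   pixel, and that raw vote *is* the segmentation — no morphological
   post-processing.

Evaluation uses the pixel-wise F-score (Dice coefficient),
2·TP/(2·TP + FP + FN), under leave-one-out cross-validation: train on
50,000 pixels sampled from N−1 images, predict the held-out image,
rotate.

Because no public PCM dataset with dense ground truth accompanies the
method, the package ships a synthetic PCM generator
(`generate_pcm_image()`, `generate_cocultured_image()`) producing
images with exact masks and the artefacts that matter: shade-off,
halos, illumination gradients, correlated background noise, and — for
the two-class task — intensity-matched textures differing only in
granularity. All tests and the acceptance script run on it.

## Worked example

```r
library(bifseg)

# six synthetic PCM images with ground truth
ds  <- generate_pcm_dataset(synthetic_spec(), 6, seed = 1)

# BIF histograms at scales 1, 2, 4 px with a 15 px window
cfg <- feature_config(scales = c(1, 2, 4), window = 15)

report <- loocv(ds$images, ds$truths, cfg,
                n_trees = 20, n_samples = 5000, seed = 2)
print(report)
#> LOOCV over 6 images: F = 0.912 +/- 0.030
#>   per image: 0.882 0.945 0.869 0.922 0.920 0.933
```

The mean F-score of 0.91 says predicted and true masks overlap at 91%
of the Dice optimum despite interiors being only 5% dimmer than
background; the per-image spread shows the score is stable across
held-out images. The BIF decomposition itself is easy to inspect:

```r
b <- compute_bifs(ds$images[[1]], sigma_b = 2)
round(table(factor(c("flat","slope","dark_blob","bright_blob",
                     "dark_line","bright_line","saddle")[b$labels + 1]))
      / length(b$labels), 3)
#>        flat       slope   dark_blob bright_blob   dark_line bright_line
#>       0.363       0.460       0.015       0.006       0.057       0.083
#>      saddle
#>       0.017
write_rgb_png(render_bifs(b), "bifs.png")   # fixed 7-colour rendering
```

A command-line interface covers the same pipeline
(`inst/cli/bifseg simulate | bifs | train | predict | evaluate |
loocv`); every run writes a `manifest.yml` from which `bifseg replay`
regenerates it bit-identically.

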