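# osteotex

Multiscale texture analysis of trabecular bone radiographs for osteoporosis
screening.

Osteoporosis erodes the spongy trabecular network inside bone long before a
fracture reveals it. On a plain radiograph that erosion is a *texture*
change: the intensity surface gets rougher at fine scales, gappier, and
locally more disordered. `osteotex` measures those three facets and turns
them into a compact, interpretable classifier — a pipeline for researchers
in radiographic bone-quality assessment who want feature-based (not
deep-learning) models that remain auditable at every stage.

## What it computes

For an image `I` viewed as a terrain of gray values:

* **Pixel-wise fractal dimension** (modified blanket method). At binning
  factor `b` the surface area around pixel `p` is the accumulated side area
  of the rescaled columns inside a fixed physical disk of radius `r_max`:
  `SA(p,b) = (1/b) * Σ_{|q−p| ≤ r_max} (|I_b(q+b·e_x) − I_b(q)| + |I_b(q+b·e_y) − I_b(q)|)`,
  and `FD(p) = 2 − slope` of `ln SA` vs `ln b` over the scale series
  `b_s = r_max/s`, `s = r_max..r_min`. Pixels in the worst 20% of fit
  residuals are discarded; the FD distribution contributes mode, sigma,
  skewness, kurtosis, and a 16-bit Shannon entropy.
* **Differential box-counting lacunarity**: box mass
  `M = ⌊max/h⌋ − ⌊min/h⌋ + 1` over `r×r` boxes (`h = 256·r/min(W,H)`),
  `Λ = E[M²]/E[M]² ≥ 1`, averaged over all `r²` grid origins; two box
  sizes (`lac_A`, `lac_B`).
* **Local-range entropy**: `v_p = max − min` gray level in a small disk;
  `H_l = −Σ P(v_i) log2 P(v_i)` over the exact integer observations in a
  larger counting disk; mode, sigma, skewness, kurtosis.

Scale parameters are picked by minimising the Davies–Bouldin index over a
candidate grid; the 11 features are ranked by a 60-round balloted,
cross-validated neighborhood-component analysis; the top 6 feed an RBF-SVM
(deterministic SMO solver, 13×13 log grid over `C` and kernel scale,
stratified 10-fold CV); evaluation reports Sn/Sp/Acc/F1/MCC, trapezoidal
AUC, and 1000-resample percentile bootstrap 95% CIs.

Because clinical images cannot ship with the package, a synthetic module
generates fractional-Brownian surfaces with known Hurst exponent `H`
(fractal dimension `3 − H`) plus dark lesion-like blobs, so every stage is
testable against ground truth.

## Worked example

```r
library(osteotex)

# a 30 + 30 synthetic cohort: healthy H = 0.7 vs osteoporotic H = 0.5 + blobs
train <- make_cohort(cohort_spec(n_per_class = 30, seed = 11), with_images = FALSE)
test  <- make_cohort(cohort_spec(n_per_class = 15, seed = 12), with_images = FALSE)

aggregate(cbind(fd_mode, lac_A, ent_sigma) ~ label, train$features, mean)
#>          label  fd_mode    lac_A ent_sigma
#> 1      healthy 2.421570 1.087489 0.1859828
#> 2 osteoporotic 2.582452 1.089506 0.1643708

res <- run_train_eval(pipeline_config(seed = 3), train$features, test$features)
res$selected
#> [1] "ent_mode"  "ent_sigma"  "ent_kurtosis"  "fd_skewness"  "ent_skewness"  "fd_mode"
res$report$auc
#> [1] 1
```

The rougher class (`H = 0.5`) shows the higher fractal-dimension mode
(2.58 vs 2.42 — fBm theory says 2.5 vs 2.3, plus a small estimator offset
that cancels between classes), slightly higher lacunarity from the blob
overlay, and the selected six features separate the held-out cohort
perfectly (AUC 1.0 — this synthetic world is easier than clinical data;
see the methods vignette for what a green test does and does not mean).

Single-image use:

```r
img <- fbm_surface(256, 0.5, seed = 42)
fd  <- residual_filter(pixelwise_fd(img, scales = scale_series(1, 4)), keep = 0.8)
fd_distribution_stats(fd)$mode       # ~2.5 = 3 - H
mean_lacunarity(img, 3)$mean_lac     # >= 1
entropy_distribution_stats(local_entropy(img, 1, 6))
```

A command-line wrapper mirrors the stages
(`inst/scripts/osteotex <enhance|features|select|train|eval|simulate>`).

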