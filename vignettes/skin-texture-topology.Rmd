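---
title: "Skin texture topology: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skin texture topology: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
persistence model and its conventions, the parameters that matter, what the
synthetic world does and does not emulate, and the choices made where the
design was genuinely open.

## The measurement model

Skin micro-relief is a network of furrows (sulci) enclosing ridge plateaus
(cristae). After binarization the furrow network is the white phase; its
loops enclose the cristae. Topology captures regularity in a way local
statistics do not: a regular honeycomb produces many holes that appear
*convergently* in a narrow threshold band, while a rough, broken texture
produces holes loosely spread over low thresholds. The package therefore
summarizes each image by the 0- and 1-dimensional persistent homology of a
superlevel filtration and regresses TEWL on those summaries or on a
vectorized form of the full diagram.

### Filtration conventions

All three filtrations share the superlevel convention: features appear as the
threshold *decreases*.

- `knn_density(image, k = 100, spacing = 10)`: grid nodes sit at pixels
  1, 1+spacing, ...; the density is the standard 2-D kNN estimate
  `k / (n_white * pi * r_k^2)`. Any monotone-decreasing function of `r_k`
  yields the same pairing order; the formula fixes the numeric scale of
  mid-life values. The distance is Euclidean, the convention of point-cloud
  kNN estimators. Nodes coinciding with white pixels (`r_k = 0`) are capped
  with the smallest positive `r_k` on the grid so the field stays finite.
  Densities are log-scaled after persistence; the log is refused whenever a
  diagram contains non-positive values, which keeps signed-distance and
  grayscale diagrams on their raw scale (whether the original study also
  log-scaled those is unstated; a flag exposes the choice).
- `signed_distance(image)`: +Manhattan distance to the nearest black pixel on
  white, − distance to the nearest white pixel on black, measured between
  pixel centers via an exact two-pass chamfer transform. Border pixels are
  ±1, so the map is 1-Lipschitz within a colour and jumps by exactly 2 across
  the border. A one-colour image receives the sentinel ±(width+height).
- `grayscale_filtration(image)`: the identity on 8-bit intensity.

### Persistence conventions

The engine (Rcpp) sweeps vertices in decreasing value order with union-find:

- **Connectivity.** Foreground 8-connectivity, complement 4-connectivity —
  the Jordan-compatible pairing on 2-D rasters, needed so that a one-pixel
  ring encloses a hole. Holes are computed by Alexander duality: a sublevel
  sweep of the same grid under 4-connectivity with a virtual outer vertex at
  −∞ attached to the frame; a finite complement component born at `b0` that
  merges at `m` is the hole `(birth = m, death = b0)`, its death position the
  component's minimum (the last pixel filled), its birth position the vertex
  whose entry closed the loop.
- **Elder rule and ties.** On a merge the component created earlier in the
  sweep survives (larger maximum; ties broken by row-major index), making
  results platform-independent.
- **Essential class.** Exactly one 0-dim class never dies; it is recorded
  with the field minimum as a death sentinel and excluded from mid-life/
  life-time statistics by default, since that death is not a measured merge.
  The component *count* still includes it: every connected component is a
  component.
- **Zero-persistence pairs** (birth = death, plateau artifacts) are dropped;
  they are invisible to Betti numbers at every threshold.

The test suite pins this model to independent oracles: a threshold-sweep
Betti counter (flood-fill labelling), an Euler-characteristic check under the
triangulated 8-connectivity complex, and a small-instance bottleneck matching
for the stability property.

## Preprocessing

`preprocess_config()` chains trim → grayscale → wavelet → Otsu → erosion.

- **Trim** takes the top-left 1400 × 1200 window (the microscope frame net of
  its scale bar). Top-left anchoring is a deterministic convention; nothing
  downstream depends on which corner is kept.
- **Wavelet reconstruction** removes uneven illumination: a 10-level
  separable 2-D transform, level 0 the final approximation, levels 1–10
  detail bands coarse → fine; bands outside the kept set are zeroed before
  inversion and the result is clipped to [0, 255]. The family is Haar
  (Daubechies-1) — the original study never names its wavelet, and Haar is
  the transform whose reconstruction behaviour is easiest to reason about;
  odd lengths are handled by repeating the trailing sample, which preserves
  perfect reconstruction.
- **Otsu** maximizes between-class variance over the 256-bin histogram;
  pixels strictly above the threshold are white. Ties break to the smallest
  maximizing threshold; a constant image keeps the constant as threshold and
  comes out all black.
- **Erosion** uses a 3 × 3 cross element with out-of-image treated as black
  (anti-extensive, monotone in iterations).

## Vectorization

The mid-life/life-time plane is partitioned per homology dimension into a
20 × 20 grid whose range (and the weighting's maximum life-time) is fitted on
the *training* diagrams only and applied unchanged to test diagrams — the
original protocol is silent on this, and fitting on all data would leak test
information. Points outside the fitted range are clipped into boundary
regions rather than discarded, so counts are conserved. Region boundaries are
half-open `[low, high)` with the last region closed. The persistence image
integrates, in closed form via separable Gaussian CDF differences (no
quadrature error), each point's isotropic Gaussian (σ = 0.1 or 1) scaled by
`life / weight_max` clipped to [0, 1]. A degenerate (single-point) range is
widened by a fixed 5% margin. The 20 × 20 partition is fitted per dimension;
sharing one box across dimensions would waste resolution because 0- and
1-dim values occupy different ranges.

## Regression pipeline

- **Near-zero-variance filter**: drop constant columns, or columns whose
  most/second-most frequent value ratio exceeds 95/5 while fewer than 10% of
  values are distinct (the conventional default of this filter).
- **PCA** on standardized columns, keeping components with variance ratio
  > 0.01 (at least one). Standardization is a deliberate choice: persistence
  image columns span orders of magnitude, and unscaled PCA would be dominated
  by the few high-mass regions.
- **Cross-validation folds are split by subject.** The original protocol
  folds on images; with three images per subject that leaks a subject's other
  images into the training folds and flatters the CV estimate. Subject-level
  folding is the package's deviation, applied consistently (the train/test
  split is also by subject).
- **Learners.** Seven algorithms behind one surface: random forest and
  gradient-boosted trees (own CART engine in Rcpp, impurity importance),
  componentwise linear L2 boosting, epsilon-SVR via the quadratic-programming
  dual, a one-hidden-layer tanh network with weight decay, elastic net
  (glmnet) and OLS. Hyperparameter grids are small, fixed and documented in
  `learner_grid()`: stand-ins for the tuning defaults the original study
  inherited from its framework but did not print. All stochastic fitting
  draws from R's RNG, so a seed fixes the whole pipeline.
- **Aggregation and metrics.** Per-image predictions are reduced to one value
  per (subject, session) by the median (mean of the two middle values for an
  even count); R² = 1 − SSE/SST, RMSE and MAE are computed on held-out
  subjects.
- **Importance back-mapping.** Impurity importance is averaged over 10
  repeated splits; with PCA, region importance is
  `sum_c importance(PC_c) * |loading_{j,c}|`, normalized to sum 1. The
  aggregation formula is not stated in the original work; absolute loadings
  weight each region by how strongly it participates in the components the
  forest actually used. Kernel and linear learners have no impurity notion
  and raise an error rather than silently substituting something else.

## The synthetic world

`generate_texture()` renders the *white-phase furrow network*: bright Voronoi
boundaries (width 6 px, intensity ~190) of a hexagonal lattice (pitch 40 px)
over darker cell plateaus (~70), plus a linear illumination gradient (span
30) and Gaussian pixel noise (sd 8), at 700 × 600 px — half the clinical
frame, chosen so a cohort fits comfortably in memory while keeping ~300 cells
per frame. The jitter parameter displaces lattice sites by a Gaussian with sd
`jitter * pitch`: jitter 0 is a regular honeycomb (one hole per cell,
appearing convergently), jitter near 1 gives heterogeneous cells whose holes
spread toward lower densities — the qualitative signature of rough,
barrier-impaired skin. `generate_cohort()` draws per-subject jitter uniformly
and sets `TEWL = 8 + 25 * jitter + N(0, 3)`, floored at 1 g·m⁻²·h⁻¹,
spanning the 8–35 range typical of cheek measurements; age is uniform on
0–64 years, sex Bernoulli(0.5), temperature ~N(20, 0.5) °C and humidity
~N(50, 3)% mirror the controlled test room. Moisture readings are generated
with a weaker, partly environmental link, matching their weaker association
with texture.

What a green test does **not** establish: the generator has no pores, hairs,
specular highlights, motion blur or focus gradients, its sulci have uniform
width and contrast, and the TEWL link is linear in a single latent parameter.
Passing the pipeline tests therefore shows the machinery is correct and
sensitive to regularity, not that clinical accuracy numbers transfer. The
erosion step defaults to 0 iterations in the synthetic pipeline: at half
scale the 6-px ridges would not survive the five cross erosions used on
full-scale clinical frames; the operation itself is exercised separately.

## Numerical choices and degenerate inputs

- Persistence requires finite fields; the degenerate caps/sentinels in the
  filtrations guarantee that.
- The permutation test used in the acceptance checks reports
  `p = (# null >= observed) / n_perm`; with the `(x+1)/(n+1)` convention 20
  permutations could never reach p < 0.01.
- `evaluate_predictions()` reports `NA` R² for zero-variance observations
  instead of dividing by zero; screens report `NA` for zero-variance
  predictors and exclude them from the FDR adjustment.
- Sample (n−1) standard deviations everywhere; a singleton dimension reports
  sd 0, an empty one `NA`.

## Known limitations

- Dimension ≥ 2 persistence, persistence landscapes/kernels, bottleneck
  distances beyond the test utility, and permutation importance are out of
  scope.
- TIFF input is not supported (no reader in the dependency set); convert to
  PNG.
- The engine's connectivity convention is internally consistent and
  oracle-tested but not guaranteed bit-compatible with other cubical
  persistence software, which may choose 4/8 rather than 8/4 connectivity or
  a different tie-break.
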