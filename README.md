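# skintda

Topological analysis of skin surface microtexture for assessing skin barrier
function from microscope images.

## The problem

Transepidermal water loss (TEWL, g·m⁻²·h⁻¹) is the standard measure of skin
barrier function, but measuring it directly is slow: subjects must equilibrate
for ~20 minutes in a climate-controlled room. The micro-relief of the skin
surface — the network of furrows (sulci cutis) enclosing ridge plateaus
(cristae cutis) — carries information about barrier integrity: regular,
honeycomb-like texture goes with low TEWL, rough and broken texture with high
TEWL. `skintda` quantifies that regularity from a cheek microscope image with
cubical persistent homology and predicts TEWL from the resulting features. It
is aimed at dermatology and skin-care researchers who have microscope images
and want a fast, interpretable barrier-function proxy.

## The method

A preprocessed image is turned into a real-valued *filtration field* f over a
pixel grid by one of three filtrations:

- **kNN density** — at grid nodes (spacing 10 px), f(x) = k / (n_w · π · r_k(x)²)
  where r_k(x) is the Euclidean distance to the k-th nearest white pixel
  (k = 100), log-scaled afterwards;
- **signed distance** — ± Manhattan distance to the opposite colour
  (+ on white, − on black);
- **grayscale** — the raw 8-bit intensity.

As a threshold t decreases from max f, the superlevel set {f ≥ t} grows.
Connected components (H₀, 8-connectivity) and holes (H₁, bounded 4-connected
complement regions) appear at a *birth* value b and disappear at a *death*
value d; each feature also records the pixel where it appears and where it is
merged or filled. Pairs are re-expressed as mid-life (b+d)/2 and life-time
b−d. Per image, fourteen summaries (counts, means and SDs of mid-life and
life-time per dimension, plus age, sex, temperature, humidity) feed a
univariate OLS screen with Benjamini–Hochberg FDR control; for prediction the
diagrams are embedded by the *persistence image* — each point contributes an
isotropic Gaussian (σ = 0.1) weighted by life-time/max life-time, integrated
over a 20×20 partition of the mid-life/life-time plane — followed by PCA
(components with variance ratio > 0.01), one of seven regressors (random
forest by default) tuned by 10×10-fold subject-level cross-validation,
subject-median aggregation over the three images per subject, and R²/RMSE/MAE
on held-out subjects. Random-forest impurity importance is mapped back through
|PCA loadings| to diagram regions, and the generators of the pairs in a
selected region can be drawn on the original pixels.

Because the study's clinical images are not public, the package includes a
synthetic generator: bright Voronoi sulci networks over a jittered hexagonal
lattice, where the jitter (irregularity) parameter generatively drives TEWL.
Every stage of the pipeline is testable against that stated world.

## Worked example

```r
library(skintda)

co <- generate_cohort(cohort_spec(n_subjects = 12, seed = 7))
d  <- image_persistence(co$images[["s001_1_1"]], "knn")
d
#> <persistence_diagram: knn, log-scaled> 538 pairs (254 components, 284 holes)

summarize_diagram(d)
#>   n_components n_holes mean_midlife_0 sd_midlife_0 ... mean_midlife_1 sd_midlife_1
#>            254     284         -12.44       0.1783 ...         -13.46       0.3938

rep <- tewl_pipeline(co$images, co$cohort, algorithm = "random_forest",
                     grid = list(), seed = 7)
rep
#> <tewl_report: tewl ~ signed persistence, random_forest>
#>   8 train / 4 test subjects
#>   held-out subject-level R2 = 0.708, RMSE = 3.883, MAE = 3.652
```

The 284 holes are the lattice cells of this low-jitter subject's texture;
their mid-life statistics (mean −13.46, sd 0.39 on the log-density scale) are
the regularity measures that screen most strongly against TEWL. The report's
R² is the subject-level coefficient of determination on the four held-out
subjects: the forest explains ~70% of the TEWL variance planted by the
generator in this small cohort. `autoplot()` and `tidy()`/`glance()` methods
exist for diagrams, screens, importance maps and reports. A thin CLI covering
synth/features/screen/train lives at `inst/cli/skintda.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch on
a synthetic cohort: the kNN-filtration univariate screen and the full
signed-distance → persistence-image → PCA → random-forest pipeline with
held-out evaluation, then writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
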