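---
title: "From cell detections to recurrence score: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From cell detections to recurrence score: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsirs)
library(dplyr)
```

## The problem

The Oncotype DX Recurrence Score (RS) is a 21-gene expression assay used to
guide chemotherapy decisions in ER+/HER2− breast cancer. It is expensive and
not universally available, which has motivated a family of models that
estimate RS from routinely collected clinicopathological variables — the
Magee equations — and, more recently, from morphological features computed on
H&E whole-slide images (WSIs). `wsirs` implements the computational chain
from cell-level detections on a WSI to an RS correlation analysis:

1. **Slide scaffolding** — tissue masking, fixed 1,024-px tiling, per-tile
   tumor and TIL (tumor-infiltrating lymphocyte) counts, density maps, and
   selection of the ten tiles with the highest tumor count.
2. **Feature extraction** — 32 image features per slide: the (tumor count,
   TIL count, tumor percentage) triplet for each of the ten tiles, the TIL
   number variance across those tiles, and a rule-based aggregated nuclear
   grade.
3. **Regression** — OLS and LASSO models of RS on the five Magee-equation-2
   variables (Nottingham grade/score, ER and PR H-scores, a HER2-equivocal
   dummy, tumor size in cm) plus three image features (densest-tile tumor
   count, TIL number variance, nuclear grade), with adjusted-R² feature
   selection.
4. **Risk evaluation** — TAILORx stratification (low < 16 ≤ intermediate ≤ 25
   < high), 3×3 concordance/step-discordance, and chemotherapy-recommendation
   discordance.
5. **Detection evaluation** — precision/recall/F1 via greedy point matching,
   IOU-cutoff contour matching, Hausdorff distance, and equivalent diameter,
   stratified by nuclear grade.

Because no real WSI cohort ships with the package, a seeded synthetic-data
module generates cell scenes and patient cohorts with known structure; every
downstream stage is tested against it.

## The feature model

### Tiling and tile-wise features

The slide canvas (40× frame, pixels) is partitioned into half-open
1,024 × 1,024-px tiles; partial right/bottom remainders are dropped so all
tiles have equal area, which keeps absolute counts comparable across tiles.
A tile counts as tissue when at least 5% of its pixels pass the tissue mask
(HSV saturation > 30 on the 8-bit scale). Each detected cell is assigned to
the unique tile containing its centre. The ten tissue tiles with the highest
tumor count — ties broken by row-major tile index for reproducibility — give
the tile order $i = 1..10$, and each contributes its triplet
$(n_t^{(i)}, n_l^{(i)}, n_t^{(i)}/(n_t^{(i)}+n_l^{(i)}))$.

### TIL number variance

Over the selected tiles the TIL number variance is the sample variance

$$V = \frac{\sum_{i=1}^{m}(n_i - \bar n)^2}{m - 1}, \qquad m = 10$$

with $n_i$ the TIL count in tile $i$. Note the square: the unsquared sum of
deviations is identically zero for any counts (a property test asserts
this), so only the squared form can be meant by a "variance", and only it
produces values on the scale seen in real cohorts (hundreds to thousands of
cells²). Slides with $m < 10$ tissue tiles use all available tiles with
divisor $m-1$ and are flagged short.

### Nuclear grading

Each tumor nucleus is graded by the ratio $r$ of its area (px²) to a
reference TIL nucleus area of 304.7 px²: grade 1 for $r < 2.5$ (ratios below
1 are clamped to grade 1 — smaller detected nuclei must still be graded),
grade 2 for $2.5 \le r \le 3.5$ (the middle bin is closed, since grade 3 is
defined strictly above 3.5), grade 3 for $r > 3.5$. "Size" is interpreted as
area: per-grade mean equivalent diameters around 26–49 px imply areas of
roughly 540–1,860 px², i.e. ratios of 1.8–6 against 304.7 px² — consistent
with the bins — whereas a 304.7-px *diameter* would be anatomically absurd
at 40×. Ratio comparisons carry a 1e-9 tolerance so areas constructed
exactly at a bin edge grade stably.

Per-cell grades from the ten tiles are pooled (top-10 pooling; a
whole-slide alternative would change only which cells are pooled) and
aggregated by a 10% cascade: grade 3 if ≥ 10% of tumor cells are grade 3,
else grade 2 if ≥ 10% are grade 2, else grade 1. With three levels the
cascade always terminates, and it is monotone: adding grade-3 cells never
lowers the slide grade.

```{r}
scene <- gen_scene(scene_config(
  canvas_width = 4096, canvas_height = 4096, n_tumor_clusters = 6, seed = 42
))
features <- extract_slide_features(scene)
ncol(features)
features[, c("t01_tumor", "t01_til", "t01_pct", "til_var", "nuc_grade")]
```

## The regression model

The dependent variable is the untransformed RS with a free intercept. OLS is
fit by `lm()`; LASSO by `glmnet` on z-scored features with an unpenalized
intercept, coefficients reported on the original scale, and a convergence
threshold tight enough that the $\lambda = 0$ limit agrees with OLS to 1e-6.
`lambda = "cv"` uses seeded 5-fold cross-validation with the one-standard-
error rule; a fixed-λ mode exists for exact reproducibility. Predictions are
deliberately unclamped — correlation metrics are computed on the raw linear
scale, and stratification applies its cutoffs to raw predictions.

Feature selection enumerates the model family actually searched in this
design: tile depth $x = 1..10$ (using the first $x$ triplets jointly), with
the TIL variance and nuclear grade each toggled, always on top of the Magee
variables; combinations are scored by training adjusted R², ties toward
fewer features (`search_feature_combinations()`).

Fit quality is reported as $R^2 = 1 - SS_{res}/SS_{tot}$, adjusted
$R^2 = 1 - (1-R^2)(n-1)/(n-p-1)$, and the Pearson correlation with a
two-sided p-value from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df.

## Risk evaluation

TAILORx categories use the 16/25 cutoffs: low is score < 16, intermediate
16–25 inclusive, high above 25; non-integer predictions are compared
directly against the cutoffs (so 25.4 is high). The 3×3 confusion matrix is
kept in high/intermediate/low order so published tables round-trip
bit-exactly; concordance, one-step and two-step discordance partition the
matrix and always sum to 1.

The chemotherapy recommendation rule — recommend when RS ≥ 26, or when
age ≤ 50 and RS ≥ 16 — is a reconstruction of the TAILORx-suggested
practice from external sources (the trial's cited guidance, not a formula
printed with the tables); every threshold is an argument so other rule
tables can be swapped in.

## Detection and segmentation evaluation

The point-matching criterion used for precision/recall/F1 is not uniquely
determined by published descriptions of detector evaluation, so the package
fixes one and documents it: candidate GT–prediction pairs within a 12-px
radius (about half a grade-1 equivalent diameter) are accepted greedily in
order of ascending distance, ties by index. Tests compare it against an
exhaustive maximum-cardinality, minimum-distance assignment oracle on small
instances.

Contour matching follows the sequential largest-IOU rule: ground truths are
scanned in index order; each takes the unassigned prediction with the
largest IOU ≥ K (ties to the lower index); a prediction already assigned to
an earlier ground truth stays with it. IOU uses exact polygon clipping
(Vatti algorithm). The Hausdorff distance is computed on polygon boundaries
densified so no segment exceeds 1 px, which bounds the discretization error
of the max–min reduction; the triangle inequality therefore holds within a
2-px slack in tests. Per-grade summaries report the mean Hausdorff distance
over matched pairs and its ratio to the mean equivalent diameter
$\sqrt{4A/\pi}$ over **all** ground-truth nuclei of that grade (not only
matched ones), at IOU cutoffs 0.1–0.9.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is exercised;
it is not tuned per test.

* **Scenes.** Tumor cells form Gaussian clusters (default 3 clusters of
  ~150 cells, spread 120 px on a 2,048² canvas); TILs are a background
  Poisson field (40 cells/megapixel) with a 4× intensity boost in a 100-px
  annulus outside each cluster's 2-SD radius, reflecting the qualitative
  observation that TIL-dense regions sit near tumor-dense regions. Nuclei
  are ellipses (axis ratio uniform in [0.7, 1], rotation uniform) whose
  polygon area exactly equals the sampled area, drawn strictly inside the
  grade bin of a grade sampled from `grade_mix`, relative to the 304.7-px²
  reference.
* **Detector simulation.** `perturb_detections()` drops each cell with
  probability `fn_rate`, jitters survivors, and adds uniform spurious cells
  with expected count `fp_rate · n` — giving scenes with known TP/FP/FN for
  the evaluation module.
* **Cohorts.** The eight model variables are sampled from marginals matched
  to a real training cohort's summary table (e.g. ER H-score mean 277 on
  80–300; densest-tile tumor count mean 346 on 140–612; HER2-equivocal
  probability 2/125), continuous features via a mean-matched Beta on the
  observed range (concentration 4, a choice that keeps realistic skew
  without degenerate pile-ups). RS is intercept + coefficients·x + Gaussian
  noise (default SD 5 RS units); the raw value is kept alongside the
  rounded-half-up, [0, 100]-clipped integer RS. The default coefficients are
  the package's own invention — chosen so typical RS lands in the realistic
  5–35 band and the TIL-variance mean·coefficient product is ≈ 0.36, the
  order reported for real cohorts — and are returned as an attribute so
  recovery tests compare estimates against the exact truth.

What the generator does **not** emulate: H&E texture, staining variability,
color normalization, scanner artifacts, segmentation-error morphology, or
any spatial statistics of real TIL infiltrates beyond the cluster/annulus
sketch. Passing tests therefore demonstrate the correctness of the
computational chain under known structure, not clinical performance on real
slides; headline correlations from real cohorts (Pearson ≈ 0.5–0.7) are not
reproducible without the original images and trained detectors, and the
package makes no attempt to imitate them.

Degenerate inputs are handled explicitly: empty configurations give empty
scenes; a cohort draw in which a feature with non-zero true coefficient is
constant (most commonly the rare HER2-equivocal dummy at small n) is
rejected as a singular design rather than silently fit.

```{r}
cohort <- gen_cohort(cohort_config(n_patients = 150, noise_sd = 5, seed = 7))
fit <- fit_rs_ols(cohort)
glance(fit)

pred <- predict_rs(fit, cohort)
agreement_stats(confusion3(stratify_rs(cohort$rs), stratify_rs(pred)))
```

## Numerical and design choices

* Coordinates are 0-based with origin top-left (x rightward, y downward) in
  the 40× frame; tiles are half-open, so a cell at x = 1,024 belongs to
  column 1, and no cell is ever counted twice.
* 20×-scanned inputs are brought to the 40× frame by an exact factor-2
  resize: bilinear for rasters, coordinate doubling (areas ×4) for cell
  records; inputs carry an explicit magnification tag and re-upscaling is an
  error.
* The saturation threshold 30 lives on the 8-bit 0–255 scale; the mask is
  invariant to whether rasters store 0–1 or 0–255 intensities.
* Tumor percentage uses detected cells of both classes in the tile as its
  denominator.
* Nottingham can be recorded as grade (1–3) or score (3–9); the column is
  used as given and the choice is the caller's metadata.
* Seeds: every generator takes an explicit integer seed and restores the
  caller's RNG state, so identical seeds give bitwise-identical output and
  library calls never perturb user code.

Problem sizes in the test-suite simulations (e.g. 100 cohorts of n = 300 for
coefficient recovery, 200 random instances for matching oracles, 4,096²-px
scenes with ~1,000–2,500 cells) were chosen as the smallest at which the
statistical checks have comfortable power; all are package choices and scale
up freely.

## Known limitations

* No pyramidal WSI formats (SVS/NDPI) and no deep-learning detector: the
  package starts from detection records (GeoJSON/CSV) and provides a
  perturbation simulator in place of a trained model.
* Published Magee-equation coefficients are not reproduced; the Magee-2
  *variable set* is used with coefficients fit to the data at hand.
* The density "count" is a raw per-tile count, not normalized by tissue area
  within the tile — consistent with a densest-tile count feature, but a
  tissue-area-normalized variant would differ on edge tiles.
* The greedy point matcher can in principle differ from the optimal
  assignment when detections are denser than the match radius; at the
  default 12-px radius on realistic nucleus spacing the two agree (tested),
  but the criterion is a package convention, not a community standard.
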