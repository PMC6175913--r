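---
title: "Stability-informed histomorphometric feature analysis"
author: "glandstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-informed histomorphometric feature analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glandstab)
```

## The problem

Automated classifiers built on histomorphometric features — quantitative
descriptors of gland architecture, shape and image texture computed from
digitized H&E tissue — can fail to generalize across institutions because
fixation, staining and scanning differ between laboratories. A feature whose
distribution shifts with the preparing site carries site signal that a
classifier will happily exploit in training and then lose on an outside
cohort.

`glandstab` implements a complete pipeline for diagnosing and defending
against this failure mode in prostate-histology-style data:

1. extract a fixed panel of 242 features per region of interest (ROI),
2. quantify each feature's **preparation-induced instability (PI)** — the
   fraction of cross-site comparisons in which its distribution differs
   significantly between sites' non-cancerous regions,
3. gate feature selection on stability (`PI < 0.25`) before selecting for
   discriminability, and
4. evaluate cross-site generalization with hold-one-site-out validation,
   comparing stability-gated selection (`FS_sd`) against purely
   discriminability-driven selection (`FS_d`).

Because multi-site pathology cohorts are rarely public, the package ships a
synthetic-data subsystem that emulates both H&E-like ROIs (with ground-truth
glands and configurable site effects) and multi-site feature tables with
known discriminative and site-shifted structure. Every downstream stage is
testable against that ground truth.

## The instability statistic

For features measured on non-cancerous regions from $m$ sites, every
unordered site pair is compared per feature with a two-sided Wilcoxon
rank-sum test at level $\alpha$ (default 0.05, configurable; the rank test
makes PI invariant under any strictly monotone transformation of a feature):

$$\mathrm{PI}(f) = \frac{\#\{\text{site pairs with } p < \alpha\}}{\binom{m}{2}}.$$

In exact mode PI therefore lives on the grid $\{0, 1/\binom{m}{2}, \dots, 1\}$;
with three training sites the only values are $0, 1/3, 2/3, 1$, so the
conventional gate threshold of 0.25 admits exactly the features with
$\mathrm{PI} = 0$. A subsampled mode (random per-site subsamples, repeated)
yields finer-grained PI values; both are exposed because the repetition
protocol that produces continuous PI values in practice is a design choice,
not something the statistic dictates. **Latent instability (LI)** — the
rejection rate over random within-site half-splits — is provided as the
no-site-effect baseline; for an i.i.d. feature it converges to $\alpha$.

Non-cancerous regions are used for PI throughout (including the grading
task) because they are numerous and their feature distributions should not
differ across sites for biological reasons; observed differences are
attributed to preparation.

## The feature panel

The 242 features comprise five families (216 gland-derived + 26 texture);
`featureManifest()` is the canonical ordered list that tests assert against.

* **Global graph (51)** — from gland centroids (microns): Voronoi polygon
  area/perimeter/chord statistics (unbounded cells excluded), Delaunay edge
  length and triangle area statistics, minimum-spanning-tree edge
  statistics, mean distance to the 3/5/7 nearest neighbors, neighbor counts
  within 40/60/80/100 µm, and three density measures. Scalar aggregates are
  mean, standard deviation, min/max ratio and the disorder statistic
  $1 - 1/(1 + \sigma/\mu)$. The family's exact composition is nowhere
  canonically enumerated in the literature it comes from; the 51 slots fixed
  here (12 Voronoi + 8 Delaunay + 4 MST + 12 kNN + 12 radius-count + 3
  density) are asserted by the manifest so the layout cannot drift.
* **Gland shape (100)** — 25 boundary measurements per gland (area,
  perimeter, area ratio to the minimum enclosing circle, convex-hull
  perimeter ratio, centroid-boundary distance statistics, smoothness,
  box-counting fractal dimension, 7 Hu invariant moments, 9 Fourier
  descriptors), aggregated across glands by mean, median, standard deviation
  and min/max ratio. Hu moments are computed from *exact polygon moments*
  (Green-theorem triangle decomposition), so translation/rotation invariance
  holds to machine precision rather than raster precision. Fourier
  descriptors are the magnitudes at frequencies 2–10 of the arc-length
  resampled complex boundary, normalized by the fundamental; normalizing
  the fundamental by itself would produce a constant feature, which is why
  the window starts at frequency 2.
* **Orientation disorder (39)** — gland orientation is the first principal
  axis of the boundary vertices against the fixed reference (1, 0), folded
  to $[0^\circ, 180^\circ)$ (ties, e.g. circles, resolve to the lower
  angle). Per sub-graph, an $18 \times 18$ co-occurrence matrix over
  10-degree bins is populated by all unordered pairs of co-member glands
  (counted symmetrically), reduced to 13 co-occurrence statistics, and
  aggregated across sub-graphs by mean, std and range.
* **Sub-graph (26)** — glands are joined when centroids are within a
  connection radius (default 200 µm; a deterministic radius rule is used in
  place of the probabilistic decaying-link constructions found elsewhere
  because it is reproducible and directly testable). The 26 statistics
  cover edge-length moments, eccentricity/diameter/radius (average and 90th
  percentile, in hops), average path length over connected pairs, three
  clustering coefficients, giant-component ratio, isolated fraction,
  end/central node counts, component counts and sizes, degree and edge
  count.
* **Haralick texture (26)** — grayscale conversion (luminosity weights),
  quantization to 64 levels over the fixed 8-bit range, symmetric
  co-occurrence matrices averaged over the four unit offsets in sliding
  windows (default 64 px window, 32 px stride), the same 13 statistics as
  the disorder family, aggregated across windows by mean and std. The
  sliding-window population is what gives the "mean/std" aggregate meaning
  for a single ROI. (The source literature is internally inconsistent about
  whether this family has 26 or 39 members; 26 — 13 statistics × 2
  aggregates — is what the 242/216 totals require, and is what this package
  fixes.)

Degenerate inputs take documented constants: a single gland gives shape
std 0 and min/max 1; an all-isolated partition gives path statistics 0; a
one-hot co-occurrence matrix gives entropy 0, energy 1, correlation 0.

## Segmentation and magnification protocol

Gland boundaries come from lumen-based segmentation: k-means with $k = 4$
(Lloyd iterations, 10 restarts, best inertia) on 10,000 sampled RGB pixels;
every pixel is labelled by its nearest centroid; the brightest centroid is
lumen, the darkest nuclei, and of the remaining two the more saturated is
stroma (the label-assignment rule is a package convention — nothing in the
method itself fixes it). Connected lumen components of at least 30 px (at
the 4 µm/px segmentation scale) are grown by morphological dilation until
the new ring is mostly nuclei-labelled or 5 steps are reached, the boundary
is smoothed by a circular 5-vertex moving average, and the polygon centroid
is taken. Inputs are rescaled to a 4 µm/px (5X-equivalent) resolution for
segmentation; shape measurements are taken at a 16 µm/px (1.25X-equivalent)
scale. The growth stopping rule, smoothing filter and minimum-size filter
are configuration, not inferred: the published description of the upstream
segmentation method does not specify them.

## Stain normalization

The Macenko-style normalizer computes per-channel optical density
$-\log_{10}((I + 1)/256)$, discards background pixels (all channels below
OD 0.15), finds the dominant OD plane by SVD, and places the two stain
vectors at the 1st/99th percentiles of the pixel angles in that plane. (The
textual description this follows conflates an NMF factorization with an SVD
step; the quoted thresholds — OD 0.15, 1st/99th percentile angles — belong
to the SVD-plane construction, which is what is implemented.) Pixels are
assigned to the stain with the larger deconvolved intensity; each stain's
intensity histogram is matched to the template by 256-bin quantile mapping;
the image is recomposed through the template's vectors. Background pixels
pass through unmodified (the source description is silent on background;
carrying it through keeps white areas white and makes self-normalization
nearly idempotent).

## Selection, gating and evaluation

Four selectors are provided: **SFS** (greedy forward selection on the joint
candidate set, objective = mean AUC of a QDA classifier over 10 seeded
iterations of 3-fold CV; the joint-set objective is standard SFS), **WLCX**
(absolute deviation of the positive-class rank sum from its null
expectation — the class-imbalance-corrected reading of "largest difference
in the sum of ranks"), **mRMR** (quartile-binned mutual information,
MID acquisition), and **ROC** (orientation-corrected empirical AUC,
$\max(A, 1-A)$, so anti-correlated features are not penalized). Ties break
by canonical feature order; all selectors are deterministic given seed.

The stability gate `stabilityGate()` excludes every feature with PI at or
above the threshold (strictly less-than survives). `holdOneSiteOut()` runs
one fold per site: PI is recomputed from the training sites' non-cancerous
rows only, the gate (for `FS_sd`) restricts candidates, selection sees only
training rows, the classifier (LDA/QDA with ridge-regularized Gaussian
discriminants, linear-kernel SVM with unit cost, or a 100-tree random
forest; features standardized with training statistics for the first three)
is trained on the top-5 features and scored on the held-out site. Nothing
from the held-out site is touched before scoring, and a mutation test in
the suite enforces that. Percent improvement is
$100 (\mathrm{AUC}_{sd} - \mathrm{AUC}_d)/\mathrm{AUC}_d$ from unrounded
AUCs.

## What the synthetic data emulates — and what it does not

`simulateRoi()` renders lumen-bearing glands — a dark nuclear annulus
around a near-white lumen on textured pink stroma — as smoothly perturbed
ellipses (glands are wavy, not conic; perfect ellipses would also make the
odd Hu moments identically zero and their aggregates meaningless). Class
presets control density, size, crowding and lumen fraction; the
poorly-formed-gland grade is emulated through lumen absence
(`lumenFraction < 1`), matching how lumenless fused glands enter a
lumen-keyed segmentation at all. Site effects are an RGB shift, contrast
scaling, Gaussian blur, a rotation in the canonical H&E optical-density
plane, and gland dropout, applied in that documented order; the identity
effect is bit-identical. Default magnitudes are free parameters — there is
no public quantitative characterization of inter-site appearance
differences to calibrate against.

`simulateFeatureTable()` generates i.i.d. Gaussian (or lognormal) baselines
with designated class effects (in within-class SD units) and designated
per-site location/scale shifts; the discriminative and unstable sets may
overlap, which is precisely the structure the gate exists to reject.
Per-site class balances are supported because site-class confounding is the
mechanism by which an unstable feature acquires *spurious* pooled-training
separation: with balanced sites, a pure site shift cannot fake class signal.
`demoGleasonTable()` bundles a 4-site grading-study analogue (28 graded +
12 non-cancerous regions per site, 60 features).

Passing tests on these generators demonstrates the statistical machinery —
calibration of PI under the null, exactness of the gate, the directional
benefit of gating under confounding — not photorealism: real H&E has
nuclei-level texture, scanner PSFs, annotation noise and within-patient
correlation (the generator defaults to one region per synthetic patient;
a `regionsPerPatient` knob exists). Results on real multi-site cohorts can
differ in magnitude from the synthetic analogues.

## Numerical choices and problem sizes

* Wilcoxon tests use the exact distribution where R's default provides it
  (small samples without ties), the normal approximation otherwise; fully
  tied samples (constant features) count as non-rejections.
* LDA/QDA covariance estimates always receive a scaled ridge
  (`1e-6 * mean(diag)`), escalated only if factorization still fails — so
  constant or collinear features never crash a fold, matching the
  documented regularized-fallback contract.
* Delaunay triangulation is Bowyer-Watson with a strict in-circle test
  (cocircular grids resolve to an arbitrary but valid triangulation);
  Voronoi cells are built independently by half-plane clipping and cells
  touching the far bounding box are excluded as unbounded.
* Percent change in the gland-removal experiment is
  $|(f - f_0)/f_0| \cdot 100$, with absolute change $|f - f_0| \cdot 100$
  when $f_0 = 0$; texture features do not depend on the gland set and are
  carried as zero change rather than recomputed.
* Simulation sizes in the test suite and acceptance script (e.g. 40 regions
  per site, 20–60 features, 50 evaluation replicates, 200 null features for
  calibration) were chosen as the smallest sizes at which the binomial
  noise of the checked rates is well inside the asserted margins.

## Known limitations

* The 51/26-member family compositions and several segmentation constants
  are package conventions where the source material names families but not
  members; the manifest makes the convention explicit and testable, but
  numerical comparability with other implementations of "the same"
  features should not be assumed.
* Only one normalization family (Macenko-style) is implemented; findings
  about normalization's effect on stability can be specific to the method.
* The renderer is not photorealistic and the segmentation is only exercised
  against it; on real slides the upstream segmentation quality dominates
  everything downstream, which is exactly the sensitivity the gland-removal
  perturbation experiment quantifies.
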