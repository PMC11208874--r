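---
title: "Berry-level cluster phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Berry-level cluster phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bunchpheno)
```

`bunchpheno` post-processes the output of an automatic instance-mask
generator applied to 2D photographs of grape clusters, and turns raw
masks into berry-level and cluster-level phenotypes. This vignette
documents the models behind each stage, the parameters that matter, the
numerical choices, and what the synthetic-data generator does and does
not emulate.

## Input model

The unit of input is a *mask record*: a COCO run-length-encoded binary
segmentation (uncompressed dialect — the first run counts background
pixels, pixels scanned column-major — with the compressed-string
dialect accepted on read), an XYWH bounding box in 0-based pixel
coordinates with the origin at the top-left and y increasing downward,
a pixel area, and the generator's predicted-IoU and stability scores.
Records arrive in JSON, one array per image, tagged with image,
cluster and view-angle identifiers. Area and bounding box are
recomputed from the decoded mask on read whenever they disagree with
the stored values, with a warning — the mask is the ground truth.

Contours are traced on *pixel edges*, not through pixel centers: pixel
$(x, y)$ owns the unit square $[x, x+1] \times [y, y+1]$, and the
traced outer boundary of a hole-free 4-connected component has a
shoelace area exactly equal to its pixel count. This makes area
bookkeeping across the pipeline exact rather than approximate. A
consequence worth knowing: the polygon perimeter of a rasterized disk
is the staircase length ($\approx 8r$, not $2\pi r$), so isoperimetric
quantities computed from raw pixel-edge contours are biased low. Where
circularity matters — selecting the size-reference circle — the
perimeter is instead measured on a 10-harmonic elliptical-Fourier
resampling of the outline, which suppresses the staircase.

## Berry shape

Per-object metrics: shoelace area, polygon perimeter, *length* = the
maximum Feret diameter, *width* = the extent perpendicular to the Feret
axis, and aspect ratio = width/length $\le 1$, so elongation maps to
small values monotonically. Millimetre values appear when a scale is
known, obtained from the reference circle as
`known_diameter_mm / Feret_px`.

Outlines are summarised by elliptical Fourier descriptors: the closed
contour is parameterised by arc length and each coordinate expanded in
a truncated Fourier series with coefficients $(a_n, b_n, c_n, d_n)$ per
harmonic. Translation is always removed. Scale is removed by dividing
by the first-harmonic magnitude. Rotation normalization (rotating the
shape and the starting point onto the first-harmonic ellipse axes, with
the phase chosen among the four candidates that maximises the aligned
semi-axis, smallest phase winning ties) is available but *off* by
default in the filtering stage: berry orientation in the image is
informative, because rachis fragments and clamp edges have consistent
orientations while berries do not. Ten harmonics are the default —
enough that the PCA downstream (10 components) is never rank-starved,
and reconstruction error on smooth berry-like outlines is well under a
pixel.

## Mask filtering

Filtering runs in three stages, in the order the quantities they need
become reliable, and the report partitions every input mask into
exactly one bin (kept, or removed by one named stage):

1. **Merged-mask removal.** A mask spanning two or more berries
   overlaps each berry's own mask almost completely while being larger
   than either. A mask is removed when at least `min_children` (2)
   other smaller masks each have containment — intersection over the
   smaller area — of at least `containment_threshold` (0.8) inside it.
   Containment rather than plain IoU drives the rule because a big
   parent dilutes IoU but not containment.
2. **Geometric filters.** Berries dominate the records, so per-image
   medians characterise a berry. Masks are removed when their area
   falls outside `area_bounds` (0.2–5 × the median), their aspect ratio
   is below `aspect_min` (0.4), their perimeter-to-area ratio exceeds
   `perimeter_area_max` (3 × the median), or their centroid lies
   farther than `max_centroid_distance` (2) units of the cluster's own
   extent from the cluster centroid. The extent is measured per axis —
   1.4 × the upper quartile of absolute offsets on x and on y, with an
   elliptical combined distance — because hanging clusters are strongly
   elongated: one isotropic radius either spares distant background
   stains or amputates tip berries. Scenes with fewer than three
   records fall back to absolute area bounds, with a warning.
3. **EFD + PCA outlier rejection.** Up to `pca_rounds` (5) rounds; per
   round the elliptical Fourier coefficients of the currently kept
   masks are recomputed, a PCA is fit on the flattened coefficients,
   and a mask is removed when its score exceeds `pca_sd_threshold` (2)
   standard deviations on any of the first `pca_n_components` (10)
   components *and* its coefficients lie at least `pca_min_deviation`
   (0.25, in units of the scale-normalized outline) from the
   coefficient-wise median shape. The iteration stops as soon as a
   round removes nothing; zero-variance components are skipped.

The minimum-deviation gate deserves its own paragraph, because the
score rule alone is not a usable outlier detector. For any population
with continuous shape variation, "beyond ±2 SD on any of 10
components" flags the tail fraction of whatever remains — about a third
per round for Gaussian-like scores — and iterating it five times
shreds a perfectly clean berry set. What makes the stage meaningful is
an effect-size requirement: ordinary berry-to-berry variation,
including the crescents of partially occluded berries, stays within
roughly a fifth of the outline scale, while rachis bits, stars, clamp
corners and merged blobs deviate by a third or more. Requiring both
statistical extremeness and a material deviation reproduces the
behaviour this stage is meant to have — a few percent of masks removed
in early rounds, then a clean stop — and is what the defaults encode.
All thresholds are exposed in `filter_config()`.

## Cluster architecture

*ECDF profiles.* Berry locations are mask centroids — robust to the
crescent shape of partially occluded berries. Positions along an axis
are shifted to start at zero, scaled so the maximum is 100, and the
empirical cumulative distribution is sampled at 100 evenly spaced
normalized coordinates. The fractions at coordinates 25/50/75 summarise
symmetry: q25 > 0.3 and q75 > 0.8 is skewed one way, q25 < 0.2 and
q75 < 0.7 the other, and q25 ∈ [0.2, 0.3], q50 ∈ [0.45, 0.55],
q75 ∈ [0.7, 0.8] counts as symmetric. Min–max scaling uses the
centroids, not the mask extremes; the berry radius border this ignores
is a constant offset that the normalization absorbs.

*Concave hulls.* The cluster outline is a k-nearest-neighbour concave
hull over the union of berry contour vertices. `concavity` maps to the
neighbour count: small values follow the point cloud into sinuses
between wings; large values smooth toward the convex hull, which is the
limiting case. The polygon is grown (k increased) until it contains
every input vertex, so containment is a guarantee, not a tendency; for
speed the construction runs on at most `max_points` (400) thinned
vertices while containment is enforced against all of them. No claim is
made that a given `concavity` equals any particular parameter of other
hull implementations — the contracts are the convex limit and
containment. Hull length is the vertical extent and width the
horizontal extent, because clusters hang vertically in an imaging rig.

*Compactness* is the summed berry area divided by the hull area. With
visible (disjoint) masks it is bounded by 1 up to rasterization slack,
and it rises monotonically as the generator packs berries more densely
— the property that makes it a density phenotype.

*Shape PCA.* Each hull outline is encoded by EFD with translation and
scale removed but rotation retained (all clusters share the hanging
orientation, so orientation differences are signal, not nuisance), and
a PCA is fit across clusters. On an ellipse sweep the first component
tracks aspect ratio nearly perfectly, which is the expected dominant
axis of cluster-shape variation; no attempt is made to reproduce any
particular dataset's variance percentages.

## Occlusion-corrected counting

From any single angle roughly half the berries of a typical cluster are
hidden. Because the visible fraction is roughly independent of cluster
size (see the generator notes below), the visible count is linear in
the true count and an ordinary least-squares calibration
$y = \beta_0 + \beta_1 x$ suffices, with $\beta_1 \approx$
1/visible-fraction $\approx 2$. The count model trains on the
max-across-angles visible count — the least occluded of the four views;
the berry-area variant trains on per-view maxima pooled over available
views. Model quality is reported as adjusted
$R^2 = 1 - (1 - R^2)(n-1)/(n-2)$ and as k-fold cross-validated $R^2$:
folds come from a seeded shuffle applied after sorting the pairs (so
the result is deterministic given the seed and invariant to row order),
and one $R^2$ is computed on the pooled out-of-fold residuals rather
than averaging per-fold values, which is unstable for small folds.
Corrected counts are rounded half-up and never pushed below the visible
count when the slope is at least 1.

Angle statistics summarise how much the visible count depends on the
view: per-cluster relative changes against the first angle, and the
mean absolute count difference between opposing (0°–180°, 90°–270°)
versus adjacent (90° apart) view pairs. Wings drive both: a lateral
ramification is visible from the two views aligned with its azimuth and
hides edge-on in the other two, so winged clusters swing by tens of
percent across angles while opposing views stay similar.

## Repeatability

Trait tables are keyed by genotype × block × vine × cluster × angle.
Cluster values aggregate to the vine by the mean, with counts first
taking the per-cluster maximum across angles (the same least-occluded
rule as the correction). Additive block effects are removed by
centering each block at its block mean — exactly, as the invariance
test asserts — and a one-way genotype ANOVA provides method-of-moments
components: $\sigma^2_g = \max(0, (MS_B - MS_W)/n_0)$ with $n_0$ the
standard unbalanced-design replicate coefficient, and repeatability
$= \sigma^2_g / (\sigma^2_g + \sigma^2_e)$, clamped to [0, 1]. A
mixed-model fit would give the same answer on balanced designs at the
cost of a heavier dependency; the estimator is affine-invariant and
recovers simulated truths monotonically. One caution from the
recovery simulations: at 100 genotypes × 3 blocks the sampling
standard error of the estimate near a truth of 0.3 is about 0.065, so
individual estimates land within ±0.1 of the truth only ~85–88 % of
the time — that is the precision ceiling of the design, not an
estimator defect.

## The synthetic-data generator

The generator exists so that every stage has ground truth without any
image downloads. What it emulates, and how:

* **Geometry.** Berries are spheres (the emulated cultivars have small
  round berries) arranged as a *single staggered shell* around a
  vertical rachis: rows of whorls at `internode_spacing` (16 px), each
  row holding as many berries as its ring allows at the packing
  distance `packing_density × 2 × berry_radius_mean`, with conical
  taper (30 %) toward the tip and the rachis length growing with the
  berry count. The shell matters: surface berries scale linearly with
  the total, which is what keeps the visible fraction flat (~0.47)
  across cluster sizes of 5–130 berries and the count correction
  linear. A volume-filling blob would make visibility fall with size.
  Berry radii are uniform on mean ± sd·√3 — bounded, as biological
  size variation is. A pairwise relaxation step guarantees the packing
  distance; infeasible packings raise an error rather than silently
  overlapping.
* **Wings.** An optional lateral lobe: a branch leaving the upper
  rachis one cluster radius out along a chosen azimuth, carrying a
  share of the berries. Viewed along its azimuth the lobe overlaps the
  main body and the z-buffer hides one behind the other; viewed
  perpendicular it adds fully visible berries. This reproduces the
  characteristic pattern — large count swings across angles for winged
  clusters, with opposing views agreeing far better than adjacent ones.
* **Rendering.** Orthographic projection (areas preserved; perspective
  adds nothing for occlusion logic) with a per-pixel z-buffer over the
  spheres: every pixel has exactly one owner, so visible masks are
  disjoint by construction and the visible count never exceeds the true
  count.
* **Detection.** A mask generator prompted on a coarse grid finds
  essentially every well-exposed berry but misses most partially hidden
  ones. The synthetic detector draws, per berry and view, a threshold
  uniform on `detection_ramp` = (0.75, 0.95) of the full disk: above
  95 % visibility a berry is always emitted, below 75 % never, with a
  linear ramp between, deterministic given the cluster seed and angle.
  Jointly with the default packing this calibrates the mean
  emitted/true fraction to ≈ 0.47 — the "about half the berries are
  hidden" regime — and keeps heavily bitten crescents rare among
  emitted records, matching the observation that denser prompt grids
  are needed to pick up partially hidden berries.
* **Artifacts.** The clamp (an elongated dark rectangle above the
  peduncle), the reference circle (far corner, ~25 × the berry area),
  thin rachis segments, irregular wobbly stains in the frame corners,
  and merged masks built as the exact union of touching berries'
  visible masks, all labelled in the ground truth. Scenes export to the
  same mask-record JSON the package reads, so the generator doubles as
  a segmenter-adapter stub.
* **Trials.** `simulate_trial()` draws value = μ + genotype + block +
  residual with independent normal effects; the residual is per
  cluster, and the truth metadata records both the cluster-level and
  the vine-mean repeatability (they coincide at one cluster per vine,
  the design used in the recovery tests).

What the generator does *not* emulate: photometric realism (flat
fills, no lighting or texture), berry shape variation beyond spheres,
perspective foreshortening, soft segmentation errors (masks are
pixel-exact), and any cultivar-specific packing calibration beyond the
~50 % visibility target. Passing tests on synthetic scenes therefore
demonstrates the correctness of the *post-segmentation logic* — codecs,
filters, descriptors, calibrations, estimators — not the performance of
any particular segmentation model on real photographs.

## Problem sizes and reproducibility

The test-suite and acceptance runs use deliberately modest sizes chosen
as representative rather than exhaustive: 30–50 artifact scenes for
filtering recovery, 200 clusters for the occlusion calibration, 100
replicates of a 100 genotype × 3 block trial per repeatability truth,
and 4-angle renders of 50 clusters for the angle statistics. All
randomness flows through explicit integer seeds (`withr::with_seed`),
so every table and figure regenerates byte-identically. Run configs for
the end-to-end pipeline are YAML (`run_pipeline()` takes a file or a
list); outputs are plain CSV/JSON with a manifest recording the config,
seeds and per-stage record counts.

## Known limitations

* The EFD+PCA stage's minimum-deviation gate (0.25 of the outline
  scale) encodes "berries differ from berries by less than a quarter of
  their outline scale"; crops with strongly dimorphic fruit would need
  a larger value.
* The concave hull is a heuristic: containment and the convex limit are
  guaranteed, strict area monotonicity in the detail parameter is not.
* Scale recovery assumes exactly one near-circular large object among
  the removed masks; two reference circles in frame would be resolved
  arbitrarily by circularity.
* Repeatability uses method-of-moments on vine means; severely
  unbalanced designs with missing blocks would be better served by a
  mixed model.
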