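---
title: "Measuring kernel processing from instance recognition output: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring kernel processing from instance recognition output: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silagekps)
```

## The measurement model

Kernel processing quality in maize silage is conventionally measured by
sieving: the Corn Silage Processing Score is the starch fraction
passing a 4.75 mm screen. The image-based surrogate implemented here
replaces the sieve with geometry. Every kernel fragment recognised in
an image — an annotated polygon, a predicted segmentation mask, or a
bounding box — is assigned a size in millimetres, and the Kernel
Processing Score of a set of fragments is

$$\mathrm{KPS} = 100 \cdot \frac{\#\{\,\text{fragments with size} < 4.75\ \mathrm{mm}\,\}}{n}.$$

Three modelling choices deserve justification.

**Why the rotated minor axis.** Sieve separators shake in three
dimensions, so a particle passes if its *shortest* diameter fits
through the screen. For a polygon we therefore fit the minimum-area
rotated rectangle and take its shorter side (`min_area_rect()`,
`instance_size_mm(mode = "rotated_minor")`). For box-only detections no
orientation information exists; the shorter side of the axis-aligned
box is used instead (`mode = "aabb_shortest"`). The axis-aligned
shortest side is always at least the rotated minor axis, so box-based
KPS is biased toward over-size fragments — this is a property of the
detector's output granularity, not of the scoring.

**Why strict inequality at the boundary.** A fragment at exactly
4.75 mm does not pass a 4.75 mm screen; the count is
`size < threshold`, and the convention is fixed and tested. Ties have
measure zero for continuous sizes but the choice matters for
constructed inputs (a 95 px square at 20 px/mm scores KPS 0, not 100).

**Why pooling, not averaging.** A sequence is the set of images
captured at one processor-gap (PG) setting. Sequence KPS pools all
fragments of all images before taking the percentage
(`sequence_kps()`), which weights images by how many fragments they
contain. Averaging per-image percentages would up-weight sparse images;
nothing in the underlying sieve protocol corresponds to that.

Pixel lengths convert to millimetres linearly (`px_to_mm()`); the
default 20 px/mm reflects a fixed-distance camera rig at 0.05 mm per
pixel and can be overridden per image.

## Geometry: algorithms and numerical choices

- **Convex hull** via `grDevices::chull` (monotone chain), reordered to
  counter-clockwise, collinear points dropped. Degenerate polygons
  (fewer than three non-collinear vertices, zero hull area) raise
  errors rather than returning degenerate rectangles.
- **Minimum-area rectangle** by rotating calipers: the optimal
  enclosing rectangle has a side flush with a hull edge, so all hull
  edge directions are enumerated and the minimal extent product wins.
  The result is normalised to `side_a >= side_b` with the long-side
  angle in `[0, 180)` degrees, removing the four-fold parameterisation
  ambiguity.
- **Tie-breaking.** Minimum-area rectangles are not always unique:
  centrally symmetric polygons (e.g. even-vertex polygonized ellipses)
  can admit two optimal orientations with *exactly* equal area but
  different aspect. Floating-point noise would then make the reported
  minor axis depend on the polygon's position. Ties (relative area
  within 1e-9) are broken toward the smaller minor axis — deterministic,
  invariant under rigid motion, and the conservative choice for sieve
  passage.
- **Mask IoU** rasterizes both polygons on the shared integer pixel
  grid (a pixel belongs to a mask iff its center lies inside the
  polygon, even-odd rule) and takes the IoU of the binary masks. This
  matches instance-segmentation benchmark practice; the discretization
  error is bounded in tests against exact rectangle-overlap arithmetic
  (within 0.02 on ~100 px shapes). Exact polygon clipping would remove
  that error but not match how benchmark masks are scored.

Tests compare the calipers result to a 0.01°-step brute-force angle
sweep. The sweep is an upper-bound oracle: the true optimum lies at a
hull-edge angle *between* grid points, where the extent function has a
kink, so the grid minimum systematically exceeds it by an amount linear
in the step. The assertions are therefore one-sided (calipers never
above the grid minimum, to 1e-6 relative) plus a discretization bound
on the gap.

## Detection evaluation

Matching follows the single-true-positive rule: detections are
processed in descending confidence order (ties by higher best-IoU, then
input order), each claiming the unmatched ground truth of highest IoU
if that IoU reaches the threshold (default 0.5); further detections
over the same ground truth are false positives. On small instances this
greedy sweep agrees with exhaustive assignment search (tested over 500
random cases with up to 4×4 instances).

Precision, recall and F1 come from pooled TP/FP/FN counts. Average
precision is the 11-point interpolated AP: detections pooled across the
dataset, ranked by score, precision interpolated at recall levels
0, 0.1, …, 1 by the maximum precision at or above each level. Pooling
dataset-wide (rather than averaging per-image APs) matches the
benchmarks this evaluation style comes from.

Degenerate inputs: precision with no detections is 0 by convention;
recall with no ground truth is `NA` and flagged, never silently 0. The
confidence cutoff for the counting metrics is configurable
(`score_threshold`, default none in `evaluate_dataset()`, 0.5 in the
KPS pipeline) because published evaluations rarely state it; it is
stamped into every report.

## Correlation analysis

Model KPS columns are compared with annotation KPS across PG sequences:
`pearson()` computes r with a two-tailed p-value from the exact
t-transform on `df = n − 2` (with 17 sequences, `r(15)`); the normal
approximation would be inappropriate at this sample size.
`shapiro_wilk()` (Royston's algorithm, via `stats::shapiro.test`)
checks the normality assumption first, and `correlation_report()`
refuses to report r when either column rejects at 0.05 unless forced —
normality is an assumption of the test, not a decoration. The
least-squares line (`linear_fit()`) summarises the calibration between
model and annotation KPS.

The package embeds a published 17-sequence reference table
(`table4_kps()`: eight models × 17 PG sequences plus annotation KPS,
values printed to 0.1). `reproduce_paper()` recomputes the per-model
average absolute error row and the full correlation analysis and
compares to the printed values. Comparison tolerances follow the
printed precision of the inputs: 0.01 for r and W, 0.5 percentage
points for 100r², and one printed ulp (0.1) for the error row — the
published row was evidently computed from unrounded per-sequence
values, while only 0.1-rounded values are printed, and the mean of 17
absolute differences of half-ulp-perturbed inputs can legitimately
move by that much. The recomputed error for the strongest model is
2.76 against a printed 2.7; all other fifteen recomputed statistics
round to their printed values exactly.

## The synthetic generator

No public image set accompanies the analysis, so every stage is
testable against a generator whose ground truth is analytic
(`synthetic_config()`, `generate_dataset()`):

- **Shapes.** Fragments are convex polygonized ellipses (12–16 vertices,
  random orientation and aspect ratio 1.2–2.5). After polygonization
  each polygon is rescaled so that its min-area-rect minor axis equals
  the sampled size *exactly*; the sampled value is stored as metadata,
  making size recovery a sharp test rather than an approximate one.
- **Size law.** Minor axes (mm) follow a lognormal distribution —
  the standard right-skewed family for comminution particle sizes —
  with location increasing in the processor gap:
  `mu(pg) = log(1.8 + 0.55·pg)`, `sigma = 0.5`. At the default 4.75 mm
  threshold this spans expected annotation KPS from about 92% (PG 1 mm)
  to about 69% (PG 3.5 mm), mirroring the contrast between small-gap
  and large-gap harvests. These parameters are illustrative defaults,
  not claims about any particular field campaign;
  `mu_log_for_kps()` inverts the law so tests can calibrate the
  sub-threshold mass exactly (e.g. to 0.9) and check the recovered KPS
  against a binomial standard error.
- **Defaults.** 17 sequences over PGs {1, 2, 3, 3.5} mm, 5 images per
  sequence, Poisson(8) fragments per image, 1000×600 px images at
  20 px/mm. Test and acceptance runs scale counts up or down per check
  (e.g. ~600–1000 instances where a binomial standard error of about
  1–1.5 percentage points is wanted); the vignette's configuration
  values are the package's own defaults for realistic sequence shapes.
- **Detector.** `detector_model()` drops instances (miss rate), jitters
  vertices (localisation error), adds Poisson clutter, and scores
  detections as `clamp(base − penalty·(1 − IoU) + noise)`, so
  confidence correlates with localisation quality. Identity settings
  (no miss, no jitter, no clutter) reproduce the truth exactly, which
  pins the end-to-end pipeline: precision = recall = AP = 100 and
  model-vs-annotation KPS correlation r = 1.
- **Reproducibility.** All randomness flows from one seed; each
  sequence draws from its own derived seed (base + 10007·index), and
  pipeline outputs embed the config hash, seed and package version.
  Re-running with the same configuration reproduces byte-identical
  reports.

**What the generator does not emulate:** occlusion and touching
fragments are allowed to overlap but not modelled, there is no stover
background or photometric variation, and fragment shapes are convex.
Passing tests therefore demonstrate that the *measurement chain* —
sizing, scoring, matching, statistics — is correct on data with known
structure; they say nothing about how well any particular recognition
model finds kernels in real silage images.

## Known limitations

- Mask IoU is rasterized, not exact; sub-pixel disagreements near 0.5
  IoU can flip a match for nearly-threshold pairs.
- Greedy matching is the standard benchmark rule; adversarial
  configurations where it is suboptimal (a detection overlapping two
  heavily-overlapping ground truths) are possible in principle, though
  absent from random small-case sweeps.
- The 60/40 dataset split is uniform at random by image; stratification
  by PG is available (`split_dataset(stratify_by_pg = TRUE)`) but off
  by default, since the original splits were not described as
  stratified.
- Sequence KPS requires at least one scorable fragment; sequences with
  none raise an error naming the sequence rather than reporting 0.
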