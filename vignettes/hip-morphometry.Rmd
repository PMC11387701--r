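---
title: "Landmark-based hip morphometry: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based hip morphometry: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipmorph)
```

## The problem

Hip morphology — acetabular dysplasia (undercoverage of the femoral head),
pincer morphology (overcoverage), cam morphology (an aspherical head-neck
junction) and abnormal neck-shaft alignment — is a leading risk factor for
hip osteoarthritis. It is quantified on AP pelvic radiographs by a small
set of standard measurements. Performed by hand these are slow and
observer-dependent; shape-model software can place a dense set of landmarks
on the bony outline automatically, after which every measurement reduces to
deterministic 2-D geometry on the landmark coordinates.

`hipmorph` implements that geometry: it takes per-hip landmark point sets
(80 points by default, in shape-model `.pts` files or CSV), computes the
eight standard measurements, applies literature thresholds to produce
radiographic morphological diagnoses, and provides the agreement statistics
(ICC, Bland-Altman, percent agreement) with which such pipelines are
validated against human observers. Landmark *detection* from pixels is out
of scope — landmarks are the input.

## Coordinate conventions

Point files use image coordinates: x to the right, y **down**. Internally
every hip is transformed once into a canonical frame — y flipped so +y
points superior, and right-side hips mirrored so +x points **lateral** for
either side (`canonicalize()`). Measurements are therefore
side-symmetric by construction, and all eight are angles or ratios, hence
invariant under translation, rotation and uniform scaling of the input
(pixel spacing is carried but never used). Orientation within the frame is
resolved anatomically — lateral from the teardrop toward the acetabular
edge, superior from the neck toward the head — so an arbitrarily rotated
radiograph measures identically.

Angles that need a pelvic reference use the horizontal reference line of
the pelvis. The landmark protocol does not pin a unique definition, so the
package uses the line through the caudal teardrop landmarks of the two
hips of one image (`pelvic_reference_axis()`); with a single hip the caller
must supply an explicit fallback (typically the image horizontal).

## The eight measurements

With `T` the caudal teardrop, `E` the lateral bony acetabular edge, `Sm`
and `Sl` the medial and lateral sourcil points, `c` and `r` the center and
radius of the best-fitting circle around the femoral head:

* **ADR** (acetabular depth-width ratio): width `B = |E - T|`; depth `A` =
  perpendicular distance from `Sm` to the line `ET`; ADR = `A/B * 1000`.
* **mAI** (modified acetabular index): signed angle between the pelvic
  horizontal and the roof line `Sm -> E`; positive when the lateral edge
  is superior (up-sloping roof).
* **WCEA / LCEA** (Wiberg / lateral center-edge angle): signed angle
  between the vertical through `c` and the line from `c` to `Sl` (WCEA) or
  `E` (LCEA); negative when the edge point is medial to the vertical, as
  in dysplastic hips. Thresholds are unaffected by the signed convention.
* **EI** (extrusion index): with lateral coordinates measured along the
  pelvic horizontal, `A = max(0, (c + r) - E)` is the uncovered head and
  `B = max(0, E - (c - r))` the covered head; EI = `100 A/(A+B)`. The head
  extremes come from the fitted circle rather than raw landmarks, which is
  robust to contour sampling density.
* **AA** (alpha angle): angle between the femoral head-neck axis and the
  line from `c` to the alpha point, where the head-neck contour leaves the
  fitted head circle (details below).
* **NSA** (neck-shaft angle): angle between the head-directed neck axis
  and the distally directed femoral shaft axis.
* **TIR** (triangular index ratio): `d/r`, where `d` is the distance from
  `c` to the contour at the station 0.5 r along the neck axis. TIR > 1
  means the contour lies outside the head circle at the station — an
  aspherical (cam) head. The literature wording can be read as `r/d` or
  `d/r`; the asphericity reading ("the distance exceeds the radius")
  matches `d/r`, which is the default, with `r/d` available via
  `measure_options(tir_orientation = "r_over_d")`.

Axes are built as follows. The head circle is a least-squares fit to the
30 head-contour landmarks (head-neck junction landmarks are excluded: in
cam hips they bias the radius): an algebraic Kasa solution refined by
Gauss-Newton orthogonal-distance iteration to 1e-9 px, exact on noiseless
arcs. The neck axis runs from the head center through the midpoint of the
narrowest neck cross-section, pairing the i-th lateral with the i-th
medial neck landmark — a deterministic reading of "through the middle of
the femoral neck". The shaft axis is the least-squares line through
midpoints of paired shaft landmarks, oriented distally; with fewer than
two pairs the shaft is treated as not depicted and NSA is reported
missing with a reason rather than a number, and report tables show the
reduced n.

### The alpha point under annotation noise

"Where the contour leaves the circle" needs a tolerance: the package uses
`r * (1 + eps)` with `eps = 0.01` (configurable). Two refinements make the
detector stable on noisy annotations while leaving noiseless geometry
untouched:

1. the departure test runs on a 3-point running **median** of the radial
   profile along the contour, which suppresses isolated landmark
   excursions without leaking a genuine junction bump onto its spherical
   neighbour (a moving average does leak, and single noisy landmarks
   otherwise fire the test long before the true junction);
2. the alpha point is the first landmark of the **last** run of
   consecutive outside landmarks — the run that persists to the neck —
   rather than the first landmark anywhere beyond the tolerance.

On noiseless contours the spherical part lies exactly on the circle, so
both refinements reduce to "first landmark exceeding the tolerance". If no
landmark leaves the circle, the last superior-contour landmark is used as
a conservative fallback. The quantization error of the alpha angle is
bounded by the contour landmark spacing (2 degrees in the synthetic
protocol). TIR similarly evaluates the station by a local linear fit of
contour distance against the axial coordinate over the four nearest
landmarks — identical to intersecting the piecewise-linear contour on
clean data (distance is constant on the spherical part), noise-averaging
otherwise.

## Diagnostic thresholds

`thresholds()` defaults follow the printed literature values, with
comparator inclusivity exactly as printed (inclusive for the `<=`/`>=`
cutoffs, strict for NSA):

| diagnosis | rule |
|---|---|
| acetabular dysplasia | ADR <= 250; mAI >= 13; WCEA <= 25; EI >= 25% |
| acetabular overcoverage | mAI <= 3 |
| pincer morphology | LCEA >= 40 |
| cam morphology | AA >= 60 |
| coxa valga / vara | NSA > 140 / NSA < 120 |

Each flag traces to exactly one measurement and is missing when its
measurement is missing. A convenience `dysplasia_any` flag combines the
four dysplasia measurements, but the per-measurement flags are primary.
All cutoffs are overridable (and echoed into output metadata by the CLI).

## Agreement statistics

`icc()` implements the two-way single-rater forms in the McGraw-Wong
formulation from the ANOVA mean squares (MSR subjects, MSC raters, MSE
error):

* absolute agreement: `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE)/n)`
* consistency: `(MSR - MSE) / (MSR + (k-1) MSE)`

The two-way random and mixed models share these point estimates; the model
argument is a reporting label. Confidence intervals are the exact F-based
constructions (Satterthwaite degrees of freedom for absolute agreement),
two-sided 95% by default. Rows with any missing value are deleted listwise
and the dropped count reported. With zero total variance the estimate is
returned missing with a reason. When both MSE and MSC vanish (identical
columns) the interval collapses to (1, 1), which is the analytic limit of
the F interval. Note that absolute agreement <= consistency holds whenever
subjects truly differ *and* raters carry a systematic component (MSR > MSE
and MSC >= MSE); on data with no rater effect the sample MSC can fall
below MSE and the two estimates cross by a sliver.

Ratings follow the conventional bands: poor < 0.50, moderate 0.50-0.75,
good 0.76-0.90, excellent > 0.90 (the printed band gap between 0.75 and
0.76 is assigned to the higher band; likewise 70/71% for percent
agreement).

`bland_altman()` reports the bias (mean difference), sd of differences and
limits of agreement at bias ± 1.96 sd (the multiplier is configurable but
1.96 is the standard). A systematic error is flagged when |bias| exceeds
2.5 degrees for the angle measurements (mAI, AA, WCEA, LCEA, NSA) or 1% of
the measurement for the ratio measurements (ADR, EI, TIR); "1% of the
measurement" is interpreted as 1% of the grand mean of the pairwise
averages, in absolute value — the phrase is ambiguous, and this reading is
documented and configurable.

`icc_sample_size()` evaluates the Walter-Eliasziw-Donner closed form for
testing a minimally acceptable reliability against an expected one with k
replicates. At the conventional design (alpha 0.05 one-sided, power 80%,
k = 2, 0.75 vs 0.90) it returns n = 26 — the same order as the ~27
subjects typical of published reliability studies of these measurements.

`reliability_report()` assembles the machine-readable analogues of a
validation study's tables from two or more aligned measurement batches:
per-measurement ICC with CI and rating, pairwise Bland-Altman rows with
systematic-error flags, and pairwise diagnostic percent agreement with
prevalences, each carrying the n actually used.

## The synthetic generator

`generate_hip()` inverts the measurement definitions: given target values
for AA, LCEA, WCEA, mAI, ADR and NSA it constructs an 80-landmark hip (and
its mirrored contralateral side) that realizes them exactly. In the
canonical frame, head center at the origin:

* head contour on a circle of radius `head_radius` (default 100 px, a
  typical adult femoral head at standard detector resolution);
* the superior junction contour leaves the circle at the target alpha
  angle via a radial bump growing linearly with polar angle past the
  station, amplitude scaled by `cam_bump_scale` and calibrated against the
  departure tolerance so that, at scale >= 1, detection triggers at the
  first junction landmark and the AA ground truth is exact;
* acetabular anchors placed on arcs of 1.15 r (bony rim) and 1.08 r
  (sourcil) to realize LCEA and WCEA; the medial sourcil and teardrop
  solved from the target mAI and ADR with an acetabular width of 2.2 r;
* neck border pairs whose narrowest cross-section midpoint lies exactly on
  the prescribed neck axis (default 45 degrees from vertical); shaft
  border pairs realizing the target NSA;
* teardrops of the two hips at equal image height, so the pelvic reference
  is exactly horizontal.

EI and TIR are *emergent*, not prescribed — prescribing them too would
over-constrain the geometry. Their ground truths are derived analytically
from the construction: EI = `100 (r - 1.15 r sin LCEA) / (2 r)` (clamped at
0), and TIR by intersecting the continuous contour profile with the 0.5 r
station. Jointly infeasible targets (a bony edge medial to the sourcil, or
an acetabular depth exceeding the roof span) raise a constructive
infeasibility error rather than silently bending the geometry.

`simulate_study()` emulates the design of a manual-vs-automated validation
study: n hips (default 30, matching the typical reliability-study size),
each annotated by every observer in every round (default 2 x 2), with
isotropic Gaussian landmark jitter standing in for annotation variability.
Two deliberate design choices:

* the default hip sampler draws targets uniformly over representative
  adult ranges (alpha 45-75, LCEA 18-45, WCEA 3-10 below LCEA, mAI 0-12,
  ADR 230-330, NSA 115-145, neck tilt 38-52) **and** varies
  `cam_bump_scale` over 1-6, so head asphericity amplitude varies
  independently of the alpha angle — without this, TIR would be an almost
  deterministic function of AA, which contradicts its role as an
  independent asphericity measure and gives it an unrealistically small
  between-hip spread;
* each observer x round displacement field is drawn from a seed that does
  not involve the jitter sd, so studies at different noise levels reuse
  the *same* standard-normal field, rescaled (common random numbers).
  Reliability comparisons across noise levels are therefore coupled rather
  than confounded by fresh sampling noise.

What the generator does **not** emulate: spatially correlated annotation
error (real landmark models err smoothly along the contour, not
independently per point), pelvic tilt and rotation, osteophytes and other
focal bone irregularities, exposure/contrast effects, and population
correlation structure between measurements. Passing the synthetic
validation therefore demonstrates that the geometry and statistics are
implemented correctly and degrade sanely with annotation noise — not that
any particular reliability level will be achieved on clinical radiographs.

## Validation performed by the package's own tests

The test suite and `scripts/acceptance.R` recompute, from scratch:
closure (100 random hips: prescribed mAI/WCEA/LCEA/NSA recovered within
0.1 degree, AA within one contour spacing, ADR within 0.5, EI within
0.5%; in practice all are at machine precision), invariance of all eight
measurements under 50 random similarity transforms and under mirroring,
equality of the ICC estimate with a direct ANOVA-summation oracle to
1e-10 on 100 random matrices plus a hand-computed offset matrix
(consistency 1, absolute agreement 10/13), a simulated 30-hip, 2-observer,
2-round study with perfect reliability and diagnostic agreement at zero
jitter and non-increasing interobserver ICC across jitter sd 0-8 px, and
the missing-NSA contract (two shaftless hips of 30 give NSA rows with
n = 28). These problem sizes keep the whole validation under a minute on
one CPU while exercising every code path; they are the sizes reported by
the acceptance script.

## Known limitations

* The 80-point role map is a packaged, editable default
  (`inst/extdata/hip80_schema.yaml`); annotation protocols differ, and the
  schema must be adapted to the protocol that produced the landmarks.
* The pelvic reference line (teardrop-to-teardrop) is one of several
  defensible conventions; a different reference shifts mAI, WCEA, LCEA and
  EI slightly.
* AA and TIR depend strongly on the head circle fit; under heavy
  annotation noise they are the first measurements to lose reliability —
  consistent with published manual-measurement experience, where AA shows
  the weakest interobserver agreement.
* All geometry is 2-D projection geometry on a single AP view; diagnoses
  that require additional radiographic views are out of scope.
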