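---
title: "Slice-based anthropometry from photogrammetric body scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-based anthropometry from photogrammetric body scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(anthroscan)
```

## The measurement problem

Hip and waist circumference are among the most used anthropometric
indicators for overweight-related conditions, and close-range
structure-from-motion (SfM) photogrammetry promises to estimate them from a
smartphone video instead of a tape measure. The catch is background noise:
close-range SfM matches features across frames, and anything visible behind
the subject — walls, furniture, other people — produces spurious 3D points
that can outnumber the subject's own surface points several times over.
Measurements taken on such a cloud are useless; measurements taken after
mask-based background removal approach the quality of a structured-light
scanner.

`anthroscan` implements the measurement side of that workflow as composable
pieces:

1. **Mask evaluation** (`mask_confusion()`, `mask_metrics()`,
   `mask_bce_loss()`, `sequence_consistency()`): scoring binary
   person-silhouette masks against manual references, plus chroma-key
   background replacement (`apply_chroma()`). Mask *prediction* is out of
   scope — masks are inputs here.
2. **Geometry I/O** (`read_point_cloud()`, `read_mesh()`, writers): PLY
   (ascii and binary little-endian), OBJ and XYZ, with centimetres as the
   internal unit and Y as the vertical axis.
3. **Registration** (`pca_align()`, `icp()`, `cloud_mesh_distances()`,
   `registration_metrics()`): aligning an SfM cloud to a reference mesh and
   summarising cloud-to-mesh distances.
4. **Anthropometry** (`scale_to_height()`, `slice_profile()`,
   `find_hip()`, `find_waist()`, `measure_body()`): the slice/ellipse
   circumference estimator.
5. **Synthetic data** (`default_body_spec()`, `mesh_from_spec()`,
   `sample_cloud()`, `add_spurious()`, `make_mask_fixture()`): parametric
   body stand-ins with exactly known ground truth, so that every stage is
   testable without any scan data.
6. **Study reports** (`error_summary()`, `calibrate()`, `run_pipeline()`).

## Mask metrics

Frame-level metrics are computed inside a region of interest: the *minimax
rectangle*, i.e. the tightest axis-aligned bounding box of the reference
mask's foreground. This keeps large empty margins from inflating accuracy.
Bounds are 1-based and inclusive, R's native indexing convention. With the
reference as the positive class, the package reports Hamming loss
$(FP+FN)/N$, Jaccard index $TP/(TP+FP+FN)$, F-measure $2TP/(2TP+FP+FN)$,
accuracy, FPR and FNR. Two identities are maintained *exactly*: accuracy is
computed as $1 - \text{Hamming}$ (they are complements by definition), and
$F = 2J/(1+J)$ holds for every confusion table. A ratio with a zero
denominator (e.g. FPR of an all-foreground RoI) is reported as `NA`, never
silently as 0, so means over frames are not corrupted.

Sequence-level consistency compares two mask sequences frame by frame with
the *full-frame* Jaccard index: this comparison contrasts two automatic
segmentations over hundreds of frames, where no manual RoI exists. The
summaries are worst-case oriented (minimum Jaccard, fraction of frames
below 0.8, maximum false-negative count), because a handful of bad frames
is what poisons an SfM reconstruction even when average quality looks fine.

The mask training loss is also provided for evaluation use:
$-\frac 1N \sum_{ij}\left[y_{ij}\log\hat y_{ij}+(1-y_{ij})\log(1-\hat
y_{ij})\right]$, with predictions clipped to $[\varepsilon, 1-\varepsilon]$,
$\varepsilon = 10^{-12}$ — large enough to keep saturated predictions
finite, small enough that the bias (about $10^{-12}$ nats) is irrelevant.

```{r mask-example}
fx <- make_mask_fixture(dilate = 2, speckle = 0.01, seed = 1)
evaluate_masks(fx$degraded, fx$reference)
```

## Registration

**PCA pre-alignment.** The cloud is centred and rotated so the principal
axes map onto (Y, X, Z) in decreasing-variance order — a standing subject's
long axis becomes vertical. Eigenvectors leave signs free; we fix them by
requiring a proper rotation (determinant $+1$) and *non-positive skewness
of the vertical coordinate*. The sign convention comes from body shape: the
legs are long and thin, so surface points thin out towards the feet and the
head-up orientation has a long lower tail (negative skewness). The X sign
is set by non-negative skewness (arbitrary but deterministic), Z follows
from the determinant. For subjects where the vertical skewness heuristic is
ambiguous (nearly symmetric bodies), `flip_y = TRUE` flips the result.

**ICP.** `icp()` alternates closest-point correspondence with the
least-squares rigid update (Kabsch/SVD). Correspondence is point to nearest
*surface* point — distances are to triangles, not vertices — computed by a
C++ kernel with an axis-aligned bounding-box tree whose contract is exact
equality with the exhaustive scan (`method = "brute"`). With exact
correspondences the per-iteration RMSE is non-increasing; iteration stops
when the improvement falls below `convergence_tol` (default $10^{-6}$ cm)
or at `max_iter` (default 50). ICP estimates no scale: unit calibration is
the job of `scale_to_height()`, keeping the two concerns separately
testable. Self-registration experiments in the test suite recover rigid
perturbations with rotations up to 30° to better than $10^{-3}$ (Frobenius
rotation error and cm translation error); beyond roughly 45° ICP can fall
into local minima, which is why `pca_align()` comes first.

**Error statistics.** `registration_metrics()` reports RMSE, mean distance
and the *population* standard deviation of the unsigned distances. The
population convention makes $\mathrm{RMSE}^2 = \mathrm{MD}^2 + \mathrm{SD}^2$
an exact identity, which the suite asserts for every report.

## The circumference estimator

Given a cloud aligned with Y vertical:

1. **Scale.** `scale_to_height()` scales uniformly about the centroid (the
   coordinate mean) so the vertical extent equals the subject's measured
   standing height. SfM clouds carry no units, so this is the metric
   anchor. Note one consequence under noise: the extreme points that define
   the vertical extent sit in the noise tails, so with $\sigma = 0.5$ cm of
   isotropic noise on a 170 cm body the span is inflated by roughly 2.5 cm
   and every circumference is biased low by about 1.4% — visible in the
   hip errors of the validation study below. This is intrinsic to the
   height-anchoring rule, not to the slicing.
2. **Slices.** `slice_profile()` cuts horizontal slices of 1 cm thickness
   at 1 cm steps (both configurable), membership in the closed interval
   $|y - y_c| \le t/2$. Slices with fewer than 6 points — the minimum that
   determines a conic — or with a degenerate fit are recorded as flagged
   gaps with the reason, never silently fitted.
3. **Ellipse fit.** Each slice's $(x, z)$ points are fitted by direct least
   squares with the ellipse-specific constraint $4AC - B^2 = 1$, using the
   numerically stable block decomposition of the constrained eigenproblem
   and centring/scaling the data first for conditioning. The constraint
   guarantees an ellipse (never a hyperbola or parabola) even on noisy or
   partial arcs. Noise-free samples are recovered to $10^{-6}$ in every
   parameter across eccentricities and rotations.
4. **Perimeter.** The circumference estimate is the Ramanujan approximation
   of the fitted ellipse's perimeter,
   $P \approx \pi[3(a+b) - \sqrt{(3a+b)(a+3b)}]$. For body-slice aspect
   ratios ($b/a \ge 0.3$) this is within $10^{-4}$ relative of the exact
   elliptic-integral perimeter, far below every other error source.
   Ramanujan's second approximation is available (`ramanujan_variant = 2`)
   and the variant in effect is recorded in every slice profile. The
   perimeter always comes from the fitted ellipse, never from a polygonal
   hull: the ellipse is robust to the sparse clouds (tens of thousands of
   points for a full body) that masked SfM produces.
5. **Hip.** Anthropometric practice puts the hip at the largest
   circumference slightly below half the subject's height. "Slightly
   below" is quantified as the band $[0.35\,H, 0.50\,H]$ (configurable);
   `find_hip()` returns the maximum-perimeter slice in the band, ties going
   to the higher slice.
6. **Waist.** There is no consensus anatomical waist definition. The
   primary rule mirrors field practice when a tape measurement exists:
   among slices in $(0.50\,H, 0.65\,H]$, take the one whose perimeter is
   closest to the anthropometrist's value, ties going to the lower slice
   (`find_waist()`). This rule *consumes* the reference, so its error
   against the same reference is partly circular — a caveat inherited from
   the workflow it reproduces. `find_waist_unsupervised()` provides the
   reference-free alternative (minimum-perimeter slice in the band, the
   natural waist of an hourglass profile); `measure_body()` selects it
   automatically when no reference is given, and records which rule ran.

Both band edges are fractions of total height and are deliberately
conservative: they bracket the hip/waist anatomy across body types while
excluding chest and thigh geometry.

```{r measure-example}
spec <- default_body_spec(170, hip_circ_cm = 100, waist_circ_cm = 85, seed = 1)
truth <- synthetic_ground_truth(spec)
cloud <- sample_cloud(spec, n_points = 40000, noise_sigma_cm = 0.5, seed = 2)
mb <- measure_body(cloud, 170, reference_waist_cm = truth$waist_perimeter)
mb
c(true_hip = truth$hip_perimeter, true_waist = truth$waist_perimeter)
```

```{r profile-plot}
autoplot(mb)
```

## The synthetic generator

`default_body_spec()` builds a single closed tube whose horizontal
cross-section at height $y$ is an ellipse with semi-axes $(a(y), b(y))$.
Choices, made once:

* **No limbs.** Arms and legs never intersect the hip/waist bands in the
  slicing procedure, and a limbless tube admits exact closed-form ground
  truth. What the generator does *not* emulate — separate legs (and the
  buttocks gap a tape measure bridges), arm geometry, pose variation,
  scanner-specific hole patterns, and the spatially correlated error
  structure of real SfM — bounds what passing tests mean: they validate
  the estimator's geometry and its noise/contamination response, not its
  anatomical fidelity on real subjects.
* **Constant aspect ratio 1.35** (side-to-side wider than front-to-back,
  typical of human trunks). With one ratio throughout, the circumference
  profile is proportional to the semi-axis profile, so the requested hip
  and waist circumferences are attained *exactly* at their control points.
* **Control points** place the hip maximum at $0.48\,H$ (just below
  mid-height) and the waist minimum at $0.58\,H$, inside the search bands;
  shoulders, neck and head taper above, thighs and calves below. A seed
  jitters the non-anchor control points by a few percent for
  subject-to-subject variety without touching the ground truth.
* **Monotone cubic interpolation** (Fritsch–Carlson Hermite with slopes
  clamped into the $[0,3]$ monotonicity box, zero at extremum knots)
  connects the control points. Shape preservation matters here: a standard
  spline — including R's `monoH.FC`, which can over/undershoot by ~0.1% at
  knots where monotonicity reverses — would move the profile extrema off
  the control points and blur the exact ground truth.
* **Surface sampling** is area-weighted uniform over mesh triangles with
  optional isotropic Gaussian noise; 0.5 cm reflects a good close-range
  SfM reconstruction, and a flat-surface test confirms the implied
  half-normal mean distance $\sigma\sqrt{2/\pi}$.
* **Contamination** (`add_spurious()`) appends uniform points in a
  *room-shaped* expansion of the cloud's bounding box: factors
  $(4, 1.5, 4)$ along $(x, y, z)$, i.e. walls a couple of body-widths out
  but the ceiling close above the head. An isotropic expansion was tried
  first and discarded: it rescales the body symmetrically, so contaminated
  estimates undershoot the truth and, pathologically, *improve* as
  contamination grows. The room-shaped box instead lets high-leverage
  background points drag the slice ellipses far outward, reproducing the
  regime observed when measuring unmasked reconstructions — errors of the
  order of a metre, growing with the spurious fraction. The default
  spurious fraction 0.84 matches the ~6× size ratio between raw and masked
  SfM clouds.

## Validation study and problem sizes

`run_pipeline()` (and `scripts/acceptance.R`) runs the full synthetic
study: 20 subjects with heights $\sim N(168, 8)$ cm, hip $\sim N(102, 8)$
cm and waist/hip ratio $\sim N(0.85, 0.05)$; clean clouds of 50,000 points
at $\sigma = 0.5$ cm; registration on 6,000-point clean clouds and their
84%-contaminated counterparts against 60×48-ring ground-truth meshes.
These sizes were chosen to match the scale of real masked SfM clouds while
keeping a full study run in minutes on one core. All randomness flows
through explicit seeds; a rerun with the same configuration is
bit-identical, and every JSON report embeds the effective configuration.

## Numerical choices, degenerate inputs, limitations

* Ellipse fits reject fewer than 6 points, collinear input, and
  non-elliptical degenerate conics with explicit errors; inside
  `slice_profile()` these become flagged gap rows.
* `pca_align()` rejects rank-deficient (collinear) clouds naming the
  degeneracy; `icp()` aborts with the iteration index if an update becomes
  non-finite.
* Tie-breaks are deterministic and documented: hip upward, waist downward.
* The BVH nearest-triangle search is an implementation detail behind an
  exact-equality contract with brute force — results never depend on the
  acceleration structure.
* Known limitations: the height-anchored scale is biased low under noise
  (see above); the supervised waist rule is partly circular by
  construction; hip estimates on real bodies read the tight anatomical
  surface, which a tape measure does not (it bridges the buttocks gap), so
  field hip errors are expected to exceed what the limbless synthetic
  bodies show.
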