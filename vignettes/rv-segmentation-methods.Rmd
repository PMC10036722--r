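---
title: "Model-based RV segmentation for non-gated perfusion SPECT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based RV segmentation for non-gated perfusion SPECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the model behind `rvspect`, the assumptions it
makes, the tunable parameters and their defaults, what the synthetic
phantom generator does and does not emulate, and the design decisions
taken where the method description leaves the implementation open.

## The segmentation model

### Why a sphere for the RV

The RV in a non-gated perfusion study is faint, thin-walled, and
crescent-shaped in short-axis slices.  Direct intensity-based
segmentation is hopeless at typical count levels, so the package fits
a *geometric* model and lets the image refine it.  The adequacy of a
sphere centred on the septal wall follows from two observations on
standard cardiac dimensions.  First, for a sphere centre placed at the
septum, the distance to the apex is $f = \tfrac12\sqrt{a^2+b^2}$ with
$a$, $b$ the LV short- and long-axis lengths; writing the sphericity
index $x = a/b$ gives $f/b = \tfrac12\sqrt{x^2+1}$, which is 1.11 at
the population end-systolic index ($x=2$) and 0.98 at the
end-diastolic index ($x=1.7$) — the sphere reaches the apex at about
the long-axis distance.  Second, with $c$ and $d$ the longest and
shortest mid-RV short-axis diameters, the centre-to-free-wall distance
$m \approx c/2$, so $m/d \approx \tfrac12\,(c/d) \approx$ 0.9–1.0.
`sphericity_ratio()` and `eccentricity_half()` expose these
identities; they are evaluated, not assumed, by the test suite.

A non-gated study averages the cardiac cycle, which suits a single
static model; the package deliberately does not attempt gated (ED/ES)
segmentation, where the spherical assumption weakens.

### LV stage

The LV is segmented first because everything in the RV stage is
*relative to the LV*: the initial sphere placement, the count
normalisation, the validity floor, and the valve plane.  The LV loop
is a faithful skeleton of the classical ellipsoid-model approach:
50%-of-regional-maximum binarisation, 26-connected cluster selection
inside a configurable "upper-right" search region (orientation
dialects vary between vendors, so the quadrant is a parameter, not an
assumption), an intra-patient threshold from the maximum of 10 × 10
averaged radial profiles, then iterative algebraic ellipsoid fits to
per-profile myocardial points until centre and semi-axes stabilise to
0.1 mm.  Two robustness details matter in practice:

* when the RV free wall exceeds half the LV maximum it merges into the
  initial cluster and can push the algebraic quadric out of the
  ellipsoid class; a moment (PCA) ellipsoid of the cluster then seeds
  the loop instead, and accepted myocardial points are floored at 0.65
  of the box maximum — justified by the method's own premise that RV
  uptake stays well below the LV peak;
* the final model is refitted once to the sub-sample-precision
  delineated mid points, because the iteration's peak samples are
  quantised to the 3.2 mm radial step.

The valve plane is the basal-most plane perpendicular to the long axis
where the circumferential mean mid-myocardial count falls below 50% of
the mid-ventricular plateau, the plateau being the median over the
middle third of the long axis.  The "mid-myocardial count
distribution" rule is stated qualitatively in the underlying method;
median-over-middle-third is this package's concrete reading, chosen
for robustness to apical thinning and basal drop-off.

### RV stage

Counts are first divided by the LV maximum, making every threshold
dimensionless: the validity floor is 0.25, the half-LV-maximum
constant `C_max` is 0.5, and the adaptive delineation threshold

$$\mathrm{thr} = \frac{0.8\,C_\mathrm{profile}}{1 - 0.4\,(C_\mathrm{max} - C_\mathrm{profile})}$$

always lies strictly below $C_\mathrm{profile}$ on the valid domain,
so the above-threshold run around the accepted maximum is never empty
(a property the tests verify on a grid).  The LV is excluded by
zeroing voxels inside the fitted epicardial ellipsoid dilated by one
voxel; the dilation prevents septal bleed-through of blurred LV
counts into RV profiles.

The iterative fit (48 × 96 profiles, validity conditions, far-off
exclusion at two voxels, algebraic sphere refit, 0.1 mm/50-iteration
convergence) follows the method description closely.  Two
implementation choices deserve notes:

* **Junction truncation.**  Profiles whose endocardial crossing abuts
  the LV-exclusion boundary are delimited by the *exclusion*, not by
  RV anatomy; their mids are biased outward and are dropped from the
  refit (and replaced by the refreshed sphere in the dense stage).
  Without this the fitted centre drifts ~1–2 mm toward the septum.
* **Batch re-initialisation.**  The workflow is semiautomatic: on "RV
  not detectable" a human operator would adjust the initial sphere.
  In unattended runs `segment_rv()` retries the initial radius over
  the fixed ladder (1, 1.2, 0.8, 1.4) × the default before giving up,
  which is the deterministic stand-in for that interaction.

### Mid-surface, masks, volumes

The dense 120 × 320 delineation is completed by replacement (invalid
directions take the refreshed sphere's radius, ± half the nominal wall
for the epi/endo offsets) and smoothed into a bivariate polynomial of
total degree 5 in $(\theta, \psi)$ — polar angle and azimuth unwrapped
about the free-wall centre — fitted by damped least squares.  The
"boundary condition" tying the surface to the LV epicardium is
implemented as weight-100 constraint points on the *junction ring*,
the directions where the LV-epicardial exit distance matches the
sphere radius within 1 mm.  An earlier variant constrained a one-voxel
band around the junction; with thousands of high-weight points the
degree-5 surface collapsed (the free-wall radius was pulled several
millimetres inward), which is why the constraint is restricted to the
thin ring — the two surfaces agree there by construction, so the
constraint stabilises without distorting.

Masks are then purely geometric: myocardium = within half a wall of
the surface, cavity = inside the endocardial surface, both clipped to
the apical side of the RV valve plane and excluding the LV (epicardial
interior and the LV's own mask).  The RV valve plane shares the LV
valve plane's tilt in the vertical long-axis view, contains the X
direction, and passes through the septal intersection with the LV
epicardium.  The cavity volume is the voxel count times the voxel
volume.  The nominal wall thickness defaults to 12.8 mm (one voxel on
each side of the mid surface): the physical RV wall is thinner than a
voxel and its apparent thickness is resolution-driven, so the mid
surface is the reliable estimate and the thickness is a display/mask
convention, exposed as a parameter.

### Quantification

The polar map defaults to 18 polar × 36 azimuth sectors (the method
description fixes no resolution; 648 sectors give several myocardium
voxels per sector at 6.4 mm sampling).  Sector values are maxima of
LV-normalised counts; the free wall (default 240° about the −X
free-wall centre, configurable) splits into equal anterior, lateral
and inferior thirds, with anterior on the −Y side.  Ratios are
reported × 100, and the classification threshold on the stress
maximal lateral ratio (30 in the clinical usage) is a parameter, not
hard-coded.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| voxel spacing | 6.4 | mm | classic 64 × 64 SPECT matrix |
| profile step | half voxel (3.2) | mm | sub-voxel crossing localisation without oversampling noise |
| validity distance | 1 voxel (6.4) | mm | stated selection condition |
| validity floor | 0.25 | LV-max fraction | stated selection condition |
| far-off distance | 2 voxels (12.8) | mm | stated exclusion rule |
| convergence | 0.1 mm, max 50 iter | | well below voxel scale |
| RV wall (mask) | 12.8 | mm | apparent, resolution-driven thickness |
| LV wall | 10 | mm | textbook LV wall |
| polar map | 18 × 36 | sectors | several voxels per sector |
| free-wall extent | 240 | degrees | covers the anatomical crescent |
| ratio threshold | 30 | % | conventional classification cutoff |

## The phantom generator

`generate_phantom()` builds what the segmentation consumes — a
reconstructed, Butterworth-filtered non-gated volume — directly in the
image domain: an ellipsoidal LV shell of unit intensity truncated at
the valve plane; an RV free wall that is the spherical shell *outside
the LV epicardium* at a configurable fraction (0.2–0.6) of LV
intensity; optional basal/apical defects with severity multipliers
0.6/0.3/0.0 (the severity levels are named but not quantified in the
underlying description; these multipliers are this package's choice);
an optional hepatic blob; 9 mm FWHM Gaussian blur (the system
resolution); a Poisson draw scaled to 100 expected counts at the LV
maximum; and a 3D radial Butterworth low-pass with order 5 and cutoff
0.5 cycles/voxel, $|H| = (1 + (f/f_c)^{2n})^{-1/2}$.  Truth masks and
the truth cavity volume are computed from the pre-degradation
geometry, so they are blur- and noise-invariant by construction.

Two generator-level design decisions:

* **Emergent crescent.**  A fixed angular wedge for the free wall
  leaves the cavity unbounded over the azimuth range between the
  wedge edge and the septum — there would be no wall separating
  cavity from background, and the truth volume becomes ill-posed.
  Instead the wall is wherever the sphere is outside the LV
  epicardium, so the crescent and its septal wrap emerge from the
  sphere–ellipsoid intersection exactly as in the short-axis anatomy
  sketch that motivates the model; an azimuthal clip remains available
  (`rv_extent_deg`) for targeted fixtures.
* **Allometric cohorts.**  `generate_cohort()` draws truth cavity
  volumes uniformly on 40–220 ml and scales the LV semi-axes by
  $(V/110)^{1/3}$ before solving the RV radius against the voxelised
  truth volume.  Hearts with large RVs have large LVs; without the
  co-scaling the fixed 1.5 × (smallest LV semi-axis) initial radius
  cannot satisfy the one-voxel validity distance across the stated
  volume range, and the method never sees the wall.

What the phantoms do **not** emulate: attenuation and scatter,
collimator-distance-dependent resolution, reconstruction (OSEM)
artifacts and noise correlations beyond the Butterworth filter,
respiratory/cardiac motion, anatomical shape variability beyond
size scaling, and extra-cardiac background beyond a single hepatic
blob.  Passing phantom tests therefore demonstrates the internal
consistency and noise robustness of the algorithm under idealised
imaging physics — not clinical-grade accuracy on patient data.

## Evaluation statistics

Dice similarity, the paired (pair-mean-denominator) and
truth-referenced MAPE forms, the coefficient of repeatability
CR = 2.77 s~w~ with s~w~ = √(Σd²/2N) and a chi-square confidence
interval (the interval construction is unstated in the source
description; chi-square on N degrees of freedom is this package's
choice), Bland–Altman limits of agreement with t-based intervals, OLS
regression and Pearson correlation (via `stats::lm()`/`cor.test()`),
and ROC analysis with the Mann–Whitney AUC (half-weight ties,
Hanley–McNeil interval, Youden-optimal threshold when none is given).
The Mann–Whitney construction equals trapezoidal integration of the
empirical ROC curve exactly; the tests assert this identity and
cross-check the AUC against an independent implementation.

## Numerical choices and degenerate inputs

Trilinear interpolation with zero padding everywhere (background
counts in MPI are near zero); voxel centres on integer grid
coordinates, all model math in mm, masks in voxel space.  Sphere and
ellipsoid fits use the algebraic (linear) formulations — closed-form
and deterministic; the geometric brute-force fit exists only as a test
oracle.  Points centred and scaled before the quadric fit for
conditioning.  Tie-breaks in local-maxima selection go to the maximum
nearest the current model surface, then first-in-order.  Degenerate
inputs fail loudly: coplanar points (sphere), fewer than 9 points or a
non-ellipsoid quadric (ellipsoid, with the moment fallback only inside
the LV loop), empty masks (Dice), single-class labels (ROC), zero
denominators (MAPE forms).  Segmentation contains no randomness;
all stochasticity lives in the phantom seeds.

## Problem sizes

The bundled experiments run at desk scale: cohorts of 20 phantoms for
the accuracy metrics (mean Dice, truth-referenced MAPE) and 20
anatomies × 2 noise realisations for repeatability, on 64³ grids.
These sizes give stable means (Monte-Carlo SE of the mean Dice ≈ 0.01)
while keeping a full run in minutes on one CPU.  Failed segmentations
are scored as complete misses (Dice 0, volume 0) in accuracy metrics;
in the paired repeatability MAPE, pairs with a failed arm are excluded
(the pair-mean denominator is undefined at zero volume) and the
usable-pair count is reported alongside.

## Known limitations

* RVs fainter than a quarter of the LV maximum are undetectable *by
  the method's own validity floor*; in cohorts drawn with intensity
  fractions down to 0.2, roughly one phantom in twenty fails outright.
  This is inherent to the count-based selection rule, not to the
  implementation.
* Severely dilated RVs violate the spherical assumption; the fit
  degrades gracefully (the polynomial surface absorbs moderate
  deviation) but the model is wrong in the limit.
* The LV long semi-axis is biased ~2–3 mm short on valve-truncated
  shells (the algebraic fit sees only ~80% of the surface).  The RV
  stage is insensitive to this — initialisation uses the short axis —
  but LV-axis consumers should be aware.
* The polynomial surface is global; a degree-5 bivariate basis cannot
  follow angular features sharper than ~30°, which is intended
  (smoothing) but means focal wall aneurysms would be bridged.
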