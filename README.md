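# rvspect

Model-based right-ventricle (RV) segmentation and quantification for
**non-gated myocardial perfusion SPECT (MPI)**, with a ground-truth
digital phantom simulator and the evaluation statistics used to
characterise segmentation accuracy and repeatability.

## The problem

In perfusion SPECT the RV wall is thin (below one voxel at typical
6.4 mm sampling and 9 mm system resolution) and accumulates only a
fraction of the tracer taken up by the left ventricle (LV), so the
LV-oriented segmentation tools that dominate nuclear cardiology ignore
it.  Yet RV uptake and RV cavity size carry diagnostic information —
elevated stress RV-to-LV uptake ratios associate with severe
left-coronary and three-vessel disease.  `rvspect` is aimed at image
analysts and physicists working with reconstructed non-gated MPI
volumes who need reproducible RV contours, cavity volumes and polar-map
uptake ratios without gating or CT.

## The method

The pipeline is semiautomatic and model-based:

1. **LV stage.**  The volume is binarised at 50% of the regional count
   maximum, the LV cluster is selected (the bounding box may be
   confirmed or replaced by the user), an intra-patient threshold is
   derived from the maximum of 10 × 10 averaged radial count profiles,
   and an ellipsoidal model is fitted iteratively to per-profile
   myocardial points until the centre and semi-axes move less than
   0.1 mm.  The valve plane is placed where the circumferential mean
   mid-myocardial count drops below half of the mid-ventricular
   plateau.

2. **RV geometric model.**  A sphere centred on the septum is an
   adequate RV model: with LV short/long axes *a*, *b* and sphericity
   index *x = a/b*, the centre-to-apex distance satisfies
   *f/b = ½·√(x² + 1)*, which evaluates to 1.11 and 0.98 at the
   population end-systolic and end-diastolic indices (*x* = 2, 1.7);
   similarly *m/d ≈ ½·(c/d)* ≈ 0.9–1.0 for the mid-RV eccentricity
   index.  The initial sphere sits at the LV centre shifted by the
   smallest LV semi-axis toward the patient's right and one fifth of
   the longest semi-axis toward the apex, with radius 1.5 × the
   smallest semi-axis; both are user-overridable.

3. **Iterative RV fit.**  With the LV excluded and counts normalised
   to the LV maximum, 48 × 96 = 4608 radial profiles are cast from the
   sphere centre.  A profile is *valid* when a local maximum lies
   within one voxel (6.4 mm) of the sphere surface **and** exceeds ¼ of
   the LV maximum (in patients roughly 2000 of 4608 qualify).  Each
   valid profile is thresholded adaptively at

       threshold = 0.8 · C_profile / (1 − 0.4 · (C_max − C_profile)),

   where `C_profile` is the accepted maximum and `C_max` = 0.5; the
   outer/inner crossings of the run containing the maximum give the
   epicardial/endocardial points and their midpoint the mid-myocardial
   point.  Points farther than two voxels (12.8 mm) from the sphere
   are *far-off* and are excluded from the algebraic least-squares
   sphere refit.  The loop repeats to a 0.1 mm tolerance.

4. **Surface refinement and masks.**  A dense 120 × 320 = 38 400
   profile delineation refreshes the sphere; points failing the
   local-maxima criterion are replaced from it.  A fifth-degree
   bivariate polynomial in the sphere's angular coordinates, fitted by
   damped least squares with septal-junction constraints, forms the
   mid-myocardial surface; dilating it by half the nominal wall
   (12.8 mm total) and clipping at the RV valve plane (tied to the LV
   valve plane) yields the myocardium mask, and the voxels inside the
   endocardial surface give the cavity mask and volume.

5. **Quantification.**  An 18 × 36 polar map takes the maximum
   normalised count per angular sector; the free wall splits into
   anterior/lateral/inferior thirds, and maximal/average RV/LV uptake
   ratios are reported on the 0–100 scale (the stress maximal ratio is
   taken within the lateral segment).

A deterministic analytic phantom generator (`generate_phantom()`,
`generate_cohort()`) emulates reconstructed MPI volumes — ellipsoidal
LV shell, partial spherical RV free wall wrapping the septum, optional
defects and hepatic activity, 9 mm Gaussian blur, Poisson counts,
Butterworth post-filter (order 5, cutoff 0.5 cycles/voxel) — with
voxel-exact ground-truth masks, and `eval_stats`-style helpers
(`dice()`, `mape_paired()`, `mape_truth()`,
`coefficient_of_repeatability()`, `bland_altman()`, `roc_analysis()`,
`regression_and_correlation()`) close the evaluation loop.

## Worked example

```r
library(rvspect)

ph  <- generate_phantom(phantom_spec(seed = 11))   # degraded phantom
ph$truth$cavity_volume_ml
#> [1] 52.16666

seg <- segment_ventricles(ph$volume)
seg$lv
#> <lv_result> semi-axes 24.8/25.6/41.8 mm, centre (261.1, 148.2, 184.9) mm
#>   valve plane z = 215.6 mm, LV max count 111.7, 12 iterations
seg$rv
#> <rv_result> sphere centre (238.9, 148.1, 177.0) mm, radius 35.7 mm
#>   2048/4608 profiles valid at convergence (3 iterations), cavity 46.7 ml

quantify_rv(seg$lv$volume, seg$lv, seg$rv)
#> <rv_quant> RV/LV uptake ratios (% of LV max)
#> # A tibble: 3 × 4
#>   segment  max_ratio mean_ratio n_sectors
#>   <chr>        <dbl>      <dbl>     <int>
#> 1 anterior      43.7       32.3        88
#> 2 lateral       46.3       33.3        97
#> 3 inferior      49.5       31.1        89
#> stress maximal ratio (lateral): 46.3
#> RV cavity volume: 46.7 ml

dice(seg$rv$mask_myocardium, ph$truth$rv_myo)
#> [1] 0.8644764
```

The true cavity volume of this phantom is 52.2 ml and the pipeline
recovers 46.7 ml; 2048 of the 4608 model-stage profiles passed the
validity conditions.  The uptake ratios sit in the 30–50 range because
the phantom's RV was painted at 40% of the LV intensity and sector
maxima ride on filtered Poisson noise.  `autoplot()` renders the polar
map as a bullseye, and `plot_slice()` overlays masks on image slices.

A thin command-line wrapper ships in `inst/cli/rvspect.R` with
`simulate`, `segment`, `quantify`, `evaluate` and `pipeline`
subcommands; semiautomatic interactions (LV bounding box, RV sphere
centre/radius) are flags.

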