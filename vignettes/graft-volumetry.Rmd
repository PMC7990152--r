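---
title: "Measuring bone-graft volume change from serial CBCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring bone-graft volume change from serial CBCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

An onlay bone graft fixed to the mandibular angle remodels over months:
osteoclastic resorption removes bone at the surface, osteoblastic
apposition adds it. In a paired internal-control trial each patient
carries a drug-treated graft on one side and a saline-treated control on
the contralateral side, and the endpoint is the within-patient difference
of volume changes between a baseline cone-beam CT (CBCT, ~2 weeks
post-op) and a 6-month follow-up. Two properties of CBCT shape the whole
pipeline:

* **Voxel values are not calibrated.** Unlike clinical CT, CBCT
  intensities carry an arbitrary per-scan gain and offset, so any fixed
  segmentation threshold is meaningless across scans. Each scan is
  therefore rescaled to mean 0 and standard deviation 1000
  (`normalize_intensity()`, population-SD denominator); every downstream
  threshold is expressed in these normalized units.
* **The two scans are not aligned.** The follow-up volume is brought into
  the baseline frame by a 6-parameter rigid transform, either supplied
  (the reproduction of a manually registered study) or estimated by
  `register_rigid()`.

The measured quantity per side is the volume (mm^3) of the largest
continuous segmented-bone component inside a region of interest that
excludes the host mandible and the titanium fixation screw
(`largest_component_within()`), evaluated at the native resolution after
segmenting at a coarser working resolution.

## Pipeline and its pinned order

`quantify_pair()` runs, in order:

1. rigid registration of normalized copies (or a supplied transform);
2. trilinear resampling of the raw follow-up onto the baseline grid;
3. *resolution matching*: the baseline is blurred with a Gaussian of
   sigma `sqrt(1/6)` voxel, the average equivalent kernel of trilinear
   interpolation, so both arms have the same effective resolution.
   Without this step the resampled arm is systematically smoother and
   every volume change acquires a negative bias of a few percent;
4. per-scan normalization to mean 0 / SD 1000 (whole-volume scope by
   default; a mask scope is available). Normalized intensities are
   snapped to a 1e-6 grid, which makes the pipeline bit-reproducible
   under per-scan affine intensity changes;
5. down-sampling to the working grid (0.16 mm; block mean for integer
   factors, Gaussian pre-smoothing plus linear interpolation otherwise);
6. metal detection (threshold 3000 normalized units, dilation 0.32 mm)
   and ROI assembly from exclusion geometry;
7. threshold level-set segmentation of both timepoints;
8. trilinear up-sampling of the level-set function to the output grid
   (0.08 mm) with re-thresholding at zero, preserving the sub-voxel
   surface;
9. largest-component volumetry (26-connectivity by default) inside the
   ROI.

Whether normalization should precede or follow registration, and whether
its scope should be masked, is not determined by the study description;
the defaults above (registration on normalized copies, whole-volume
scope) are this package's pinned choice and both scopes are exposed.

## The threshold level set

Segmentation evolves a signed distance field `phi` (voxel units, negative
inside) under

```
phi <- phi - dt * (w_p * F * |grad phi|_upwind - w_c * kappa * |grad phi|)
```

with the threshold-derived speed `F = I - low` below the window midpoint
and `F = high - I` above it: positive strictly inside the window
`(low, high)`, zero exactly at the thresholds, negative outside. Defaults
are the study settings `low = 300`, `high = 600`, curvature weighting
`w_c = 0.6`. Numerical choices that needed pinning:

* **Speed scale.** `F` is divided by the window half-width
  `(high - low)/2` (its largest attainable positive value) and clamped to
  [-1, 1], so the CFL-limited time step `0.45/(1 + w_c)` is valid on any
  intensity scale and "fully in-window" always means unit front speed.
* **Sparse-field saturation.** Within the narrow band, `phi` saturates at
  +-1 voxel. Away from the zero crossing the field is flat, so updates
  vanish once the front stops; without saturation a nonzero interior
  speed drifts `phi` forever and the RMS stopping rule can never fire.
  The band (half-width 4 voxels) and the true signed distance are rebuilt
  by an exact Euclidean distance transform every 20 iterations.
* **Stopping.** Convergence requires the RMS applied update to fall
  below `rms_tolerance` (default 0.001) *and* an unchanged voxel
  classification since the last reinitialization; the second condition
  rejects fronts stalled at the band edge. A front whose classification
  is unchanged across a whole reinitialization window is also accepted as
  stationary (sub-voxel limit cycles otherwise spin until the iteration
  cap).
* **Initialization.** The in-window voxel set, intersected with the ROI
  and opened with a 1-voxel ball (removing isolated noise voxels), is
  converted to a signed Euclidean distance with a half-voxel offset so
  the zero level lies on voxel faces. The window is inclusive at both
  ends for the initializer while `F` is zero exactly at the thresholds;
  threshold-valued voxels are therefore decided by curvature.
* **Hard exclusion.** Inside `segment_bone()` the speed outside the ROI
  is set to maximal retreat: the mandible and hardware must never enter
  the segmentation, which also keeps the active band small.
* **Curvature.** Mean curvature from central first/second differences,
  clamped to +-1/voxel (the grid's resolvable curvature).

With `w_c = 0` on noiseless data the converged classification equals
plain double thresholding exactly; this is the module's principal oracle
and a unit test. Digital spheres of radius >= 10 voxels are recovered
within 3% of the analytic volume at the default parameters.

## Rigid registration

The metric is the mean squared intensity difference over the fixed-grid
voxels that map inside the moving field of view, legitimate here only
because both inputs are normalized first. Restricting the average to the
overlap matters whenever anatomy crosses the field boundary: the
fill-vs-tissue mismatch in the truncation band otherwise dominates the
metric and anchors the optimum at zero motion (an overlap floor of 10%
prevents the degenerate shrink-the-overlap solution). Initialization is
by moments -- translation from the two intensity centers of mass, refined
by an exhaustive coarse translation grid (+-6 mm, 1.5 mm steps, at
decimation 8) because the center-of-mass estimate is itself biased by
boundary truncation -- plus a coarse rotation grid probe. The
optimization proper is a three-level pyramid (decimation 4, 2, 1) of
derivative-free Nelder-Mead searches. Every level is Gaussian-smoothed
with sigma `max(1, factor/2)` voxels -- including the finest: on noisy
scans the interaction of interpolation with independent voxel noise
ripples the metric with local minima that trap the simplex several
degrees from the optimum, and a one-voxel smoothing removes the ripple
while leaving the sub-voxel optimum in place. The full-resolution level
is genuinely needed: the phantom scene is nearly symmetric under rotation
about the screw axis, and only fine-scale detail pins that angle. At
that level the metric is evaluated on every second fixed voxel (the
moving image stays at full resolution, so interpolation preserves
sub-voxel information), and the Nelder-Mead search is restarted -- the
simplex re-inflated around the current best -- while each restart still
improves the loss: the weakly determined rotation and its compensating
translation form a long curved valley in which a single simplex
collapses long before the bottom.
Registration never returns a transform with a higher full-resolution loss
than its initialization, and reports initial and final losses so a caller
can detect convergence to a poor optimum when started outside the capture
range (~10 mm). Rotations are Euler angles in degrees applied x, then y,
then z, about the fixed volume's grid center; this convention is written
into transform JSON files.

## The digital phantom

`phantom_spec()` describes a 20 mm cube at 0.16 mm spacing (125^3 voxels,
the study's working resolution; 0.08 mm is available where native-grid
behavior matters): a mandible slab (trabecular interior, 1.2 mm cortical
shell on the buccal face), a 10 x 10 x 4 mm cortical onlay graft on that
face, a titanium screw through graft into slab, the mandibular (inferior
alveolar nerve) canal running obliquely through the trabecular interior,
and soft tissue elsewhere. The canal is not decoration: an idealized flat
slab with an axis-aligned block graft is nearly symmetric under rotation
about the screw axis, leaving that rotation statistically unidentifiable
to any intensity metric; the oblique canal -- a prominent feature of real
mandibular CBCT in exactly this region -- anchors it.
Default attenuations (soft 0, trabecular 54, cortical/graft 60, metal
2100 arbitrary units) were calibrated once so that the *normalized*
default scene lands where the study's thresholds expect tissue: soft
tissue near -230, trabecular near 370, cortical/graft near 440 (inside
the 300-600 window), metal near 20000 (far above the 3000 metal
threshold). The point-spread blur is 0.08 mm, noise sigma 4 raw units
(~7% of the bone/soft contrast), per-scan gain/offset default to
identity, and the follow-up misalignment defaults to (2, -1.5, 1) deg /
(1.5, -1, 0.8) mm, a realistic repositioning error within the 5 mm / 5
deg regime. The default programmed volume fraction is 0.5, matching the
~50% graft loss conventionally expected without antiresorptive
treatment.

Programmed volume change thresholds the graft's Euclidean distance
transform at the offset whose level set has the target volume; voxels
tied at the critical distance (a box graft has tied whole planes) are
admitted in deterministic voxel order until the count is exact, so
ground-truth volumes are exact voxel arithmetic. Growth is restricted to
soft tissue. The uniform surface offset is a modeling choice; real
remodeling geometry is unknown.

The misaligned follow-up is re-rasterized *geometrically*: analytic slab
and screw in back-transformed coordinates, the graft via sub-voxel
interpolation of its signed-distance field. Resampling the rendered image
instead would add a second, purely numerical smoothing that no real
scanner applies, and that artifact (not the scene) would dominate the
follow-up's measurement bias.

All noise comes from R's Mersenne-Twister generator under a per-scan
seed; every generator output is reproducible from `seed` alone.

What the phantom does *not* emulate: beam hardening and metal streaks,
scatter, spatially varying noise, realistic anatomical shape, partial
trabecular microstructure. Passing phantom tests therefore validates the
measurement chain's geometry, normalization and convergence behavior, not
its robustness to reconstruction artifacts of real CBCT.

## Paired statistics

`build_records()` joins each patient's four volumes (treated/control side
at baseline/6 months) and computes changes, percent changes and the
paired difference; patients lacking any volume are excluded with a
warning. Conventions, each of which is pinned by cross-checking the
published numbers and audited by a test:

* descriptive SDs and Cohen's d use the **population** (n) denominator --
  the sample convention reproduces none of the printed SDs (87 vs 82 on
  the treated-side changes);
* the t statistic uses the **sample** (n-1) SD, as standard;
* the group percent change is the **mean of per-patient percents**, not
  the pooled-volume percent;
* the published "95% confidence interval" around the mean paired
  difference reproduces only as `mean +- 2 x population SD`; it is
  reported as a *dispersion interval* under that label, alongside the
  conventional t-based CI (`mean +- t_{0.975, n-1} s / sqrt(n)`), which
  is roughly half as wide;
* p values are two-sided; presentation rounding (integers for volumes
  and percents, 2 decimals for d, 5 for p) happens only in
  `render_report()`.

The type-I-error simulation (`run_trial()` with equal fraction
distributions on both sides) runs at the measurement level: volumes are
drawn from a calibrated truncated-normal model with an additive
measurement error, making the two sides exchangeable so the paired null
holds exactly. A full-imaging version of that simulation would require
hundreds of phantom segmentations while exercising exactly the same
statistical path; the imaging chain is validated separately on phantoms
with programmed effects, including a small imaging trial.

## Problem sizes and runtime choices

The validation suite runs phantoms at 125^3 working-resolution voxels
with measurement at 250^3, registration pyramids down to 31^3, brute-force
oracle comparisons (distance transforms, component labeling) on grids up
to 8^3, and 20-trial null simulations at the measurement level. These
sizes keep a full run at desk scale while leaving every mechanism -- the
narrow band, the pyramid, the order-statistic volume targeting --
genuinely exercised.

## Known limitations

* The level-set equilibrium on noisy data can end in a sub-voxel limit
  cycle; the stationary-classification rule stops it, but the `converged`
  flag may be FALSE at the iteration cap with a perfectly usable
  segmentation (the report carries iterations and final RMS).
* Absolute volumes carry a resolution-dependent edge bias (the 300
  normalized-unit crossing sits inside the blurred bone surface); the
  paired *change* is much less affected, which is the endpoint the
  design measures.
* Only axis-aligned volume geometry is supported; oblique direction
  matrices are rejected at read time rather than silently handled.
* Registration recovers misalignments whose rotation and translation
  magnitudes stay within the ~5 deg / 5 mm repositioning envelope to a
  median of well under half a working voxel and half a degree; individual
  runs can settle a degree or two away in the weakly determined rotation
  when the noise draw is unfavorable, which the reported final loss
  exposes. Beyond the capture range of the grid-probe initialization
  (~6 mm / ~6 deg) the result is a local optimum by construction.
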