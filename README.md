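# graftquant

Serial cone-beam CT (CBCT) volumetry of mandibular bone grafts for paired
internal-control trials.

When an onlay bone graft is fixed to the mandible, part of it is resorbed
over the following months; antiresorptive treatment (e.g. soaking the
graft in an ibandronate solution) is hypothesized to prevent that loss. In
an internal-control design each patient carries a treated graft on one
side and a saline control contralaterally, and the endpoint is the paired
difference of 6-month volume changes. `graftquant` implements the full
measurement and analysis chain for such a trial:

* **Imaging.** Rigid registration of the follow-up scan to baseline
  (automatic, or a supplied transform for manually registered studies);
  per-scan intensity normalization to mean 0 / SD 1000 (CBCT voxel values
  are not calibrated Hounsfield units); exclusion masking of the host
  mandible and titanium hardware; threshold level-set segmentation of
  grafted bone (window 300–600 normalized units, curvature weighting 0.6)
  on a 0.16 mm working grid, up-scaled back to 0.08 mm; the graft volume
  is the largest continuous segmented component inside the mask,
  `count × h³` mm³.
* **Statistics.** Per-patient records from the four volumes
  (`V0, V6` × treated/control), group means and population SDs, the
  paired t test `t = d̄/(s_d/√n)` with `df = n − 1`, paired Cohen's
  `d = d̄/σ_d` (population denominator), a `d̄ ± 2σ_d` dispersion
  interval and the conventional t-based 95% CI.
* **Validation.** A digital phantom of the mandible-angle scene
  (slab + cortical graft block + screw) with programmed resorption or
  apposition, known ground-truth volumes, rigid misalignment, blur, noise
  and per-scan gain/offset, used to verify the end-to-end chain recovers
  programmed percent changes within a few points.

The methods vignette (`vignettes/graft-volumetry.Rmd`) documents the
model, the numerical choices and the phantom's scope.

## Worked example: the trial statistics

The package ships the measured graft volumes of the trial it implements
(nine analyzed patients; one further patient has baseline volumes only
and is excluded automatically):

```r
library(graftquant)
records <- build_records(load_graft_volumes())
#> Warning: excluded patients with incomplete volumes: 8606
summary <- summarize_records(records)
summary
#> Paired internal-control summary (n = 9 patients)
#>   treated:  change +109 +/- 82 mm^3 (+35% of baseline)
#>   control:  change -146 +/- 87 mm^3 (-59% of baseline)
#>   paired difference: 254 +/- 108 mm^3; t(8) = 6.64, p = 0.00016
#>   Cohen's d = 2.35; dispersion interval 38-471 mm^3; 95% CI 166-343 mm^3
```

Treated grafts *gained* volume on average while every control graft lost
volume; the mean within-patient advantage of the treated side is 254 mm³
with a very large effect size. `render_report(records)` produces the
per-patient table with presentation rounding.

## Worked example: an imaging run with known truth

```r
spec <- phantom_spec(followup_volume_fraction = 0.5)  # 50% resorption
pair <- generate_pair(spec)
res  <- quantify_pair(pair$baseline, pair$followup, roi = pair$roi)
res$pct_change
#> [1] -52.1
100 * (pair$truth$graft_volume_followup /
       pair$truth$graft_volume_baseline - 1)
#> [1] -50
```

The phantom pair is misaligned by 2°/1.5 mm-scale motion and carries
blur and noise; the measured percent change lands within a few points of
the programmed truth, with the recovered transform in `res$transform`.

A thin command-line wrapper over these functions is available as
`scripts/graftquant.R` (subcommands `simulate`, `register`, `segment`,
`measure`, `stats`, `run`).

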