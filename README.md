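# DixonMuscle

Muscle-composition quantification from chemical-shift (Dixon) water–fat MRI
of the lower leg, for researchers studying fatty infiltration of skeletal
muscle — in particular two-group designs comparing adults with bilateral
spastic cerebral palsy (BSCP, stratified by GMFCS mobility level) against
typically developing (TD) controls.

From co-registered water and fat volumes and ROI masks (subcutaneous fat,
muscle compartment, and the five calf muscles MG, LG, SOL, TA, TP) the
package computes, per subject:

* **IntraMF** per muscle and **IMAT** for the compartment — the fat
  fraction

  `%Fat = 100 · I_fat / (I_fat + I_water)`

  over ROIs eroded with a 2-pixel (4.0 mm) structuring element to remove
  boundary partial-volume fat;
* **SF/M = SF volume / muscle volume**, from the un-eroded masks;
* a scan–rescan **reproducibility** metric: the per-muscle SD of IntraMF
  across repeat acquisitions, averaged over muscles.

Around this core it provides: a synthetic leg-phantom simulator with known
per-voxel fat fraction (controllable noise, T1 bias, intermuscular seams,
whole cohorts with subject metadata); four-point water–fat separation from
multi-echo complex signals (so the pipeline can start upstream of vendor
reconstruction); NIfTI/CSV/YAML I/O with strict mask-hierarchy validation;
the group-comparison statistical battery (KS + Levene assumption checks,
pooled t-tests, two-way ANOVA with Tukey post-hoc, median tests,
Kruskal–Wallis, Pearson correlations); and a seeded end-to-end pipeline
with a run manifest.

## Worked example

```r
library(DixonMuscle)

# simulate a 10 + 10 cohort at desk scale and quantify every subject
spec <- cohortSpec(gridShape = c(48L, 48L, 8L), outerRadiusMm = 40,
                   sfThicknessMeanMm = c(TD = 6, BSCP = 9),
                   sfThicknessSDMm = c(TD = 1.5, BSCP = 2.5))
sim    <- simulateCohort(spec, seed = 11)
cohort <- quantifyCohort(sim)
aggregate(cbind(intramf_mean, imat, sf_m) ~ group, cohort, mean)
#>   group intramf_mean     imat      sf_m
#> 1  BSCP    15.795604 26.28931 0.6996885
#> 2    TD     5.255108 16.44589 0.3972144

report <- runStatsBattery(cohort)
report$anovaTwoWay$effects$gmfcs$p   # 9.11e-06
report$medianTests$imat$p            # 1.08e-05
report$physical$mass_kg$ttest$p      # 0.224
```

The affected group sits ~10 percentage points above the controls in mean
IntraMF (the configured simulation shift), IMAT exceeds IntraMF because the
compartment ROI includes the fatty inter-muscular seams, and body mass does
not differ between groups — so the IntraMF difference is detected while the
demographics stay quiet. A single subject prints as:

```r
attr(cohort, "results")[[1]]
#> FatQuantResult
#>   IntraMF MG :  10.96%
#>   ...
#>   IMAT       :  23.85%
#>   SF volume  : 81.9 cm^3; muscle volume: 73.2 cm^3; SF/M = 1.119
#>   (erosion radius 2 px, disk, per_slice_2d; Eq. mode 'summed')
```

A full configured run (`runPipeline(runConfig(...))`, or
`Rscript inst/scripts/dixonmuscle.R run --config run.yaml`) writes
`results.csv`, `stats.json` and a `manifest.json` recording the seed,
config digest and every analysis setting; the same seed reproduces the run
bit for bit.

See `vignettes/dixon-muscle-quantification.Rmd` for the measurement model,
the erosion and aggregation conventions, the confounder simulations, and
every numerical design choice.

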