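---
title: "Quantifying muscle composition from Dixon water–fat MRI"
author: "DixonMuscle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying muscle composition from Dixon water–fat MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DixonMuscle)
```

## The measurement problem

Chemical-shift (Dixon) MRI exploits the ~3.4 ppm resonance difference
between water and fat protons: multi-echo gradient-echo acquisitions sample
the two species at different relative phases, from which separate water and
fat images are reconstructed. The fat fraction of a region is then

$$\%\mathrm{Fat} = 100 \times \frac{I_{fat}}{I_{fat} + I_{water}},$$

the fat signal normalised by the total signal from all mobile protons.
Applied to the lower leg this yields three complementary descriptors of
muscle composition:

* **IntraMF** — the fat fraction inside an individual muscle's ROI
  (medial/lateral gastrocnemius, soleus, tibialis anterior, tibialis
  posterior), a composite of intra- and extramyocellular lipid;
* **IMAT** — the fat fraction of the whole muscle compartment beneath the
  fascia, which additionally includes the fat in inter-muscular seams;
* **SF/M** — the subcutaneous fat volume divided by the muscle compartment
  volume, a normalised measure of subcutaneous adiposity.

Muscle composition measured this way is of particular interest in bilateral
spastic cerebral palsy (BSCP), where muscles are small and weak and
sedentary behaviour may drive fatty infiltration with functional and
cardio-metabolic consequences. The package implements the full measurement
chain and the group-comparison statistics for a two-group design (BSCP
stratified by GMFCS mobility level vs typically developing controls), and —
because clinical images of this kind are rarely shareable — a synthetic leg
phantom with known ground truth against which every stage is validated.

## Anatomy of the pipeline

1. **Phantom** (`phantomSpec()`, `makeLegPhantom()`): a stylised leg
   cross-section extruded along z — a subcutaneous fat ring, a muscle
   compartment holding five angular-sector muscles separated by
   intermuscular fat seams, and bone excluded from all ROIs. Every voxel
   carries a true fat fraction and proton density.
2. **Rendering** (`renderWaterFat()`, `renderEchoes()`,
   `simulateRepeats()`, `simulateCohort()`): noiseless water/fat channels
   are $(1-f)s_0$ and $f s_0$; optional confounders are Gaussian or Rician
   channel noise and a multiplicative T1 bias $\beta \ge 1$ on the fat
   channel. `renderEchoes()` instead synthesises the complex single-peak
   signal $S_n = (W + F e^{i\phi_n}) e^{i2\pi\psi t_n}$ at each echo.
3. **Separation** (`separateDixon()`): per-voxel least squares under the
   same signal model, linear in $(W, F)$ once the off-resonance field
   $\psi$ is known; $\psi$ can be supplied or estimated.
4. **Quantification** (`erodeMask()`, `fatFraction()`,
   `quantifySubject()`, `reproducibility()`): masks are eroded, intensity
   ratios formed, volumes computed, and scan–rescan precision summarised.
5. **Statistics** (`runStatsBattery()` and the individual tests): the
   group-comparison battery with assumption checks.
6. **Pipeline** (`runConfig()`, `runPipeline()`): one seeded, manifested
   run from config to results CSV and stats JSON.

## Parameters that matter, and their defaults

| Parameter | Default | Why |
|---|---|---|
| voxel size | 2.0 × 2.0 × 4.0 mm | the in-plane/slice geometry of the targeted calf protocol |
| slices | 27 | 27 × 4.0 mm = 10.8 cm, approximating an 11 cm section; the slice count itself is configurable |
| echoes | 4, TE₀ 2.3 ms, ΔTE 1.0 ms, 3 T | four-point gradient-echo protocol |
| fat shift | 3.4 ppm, single peak | the dominant methylene peak; multi-peak fat models are out of scope |
| erosion | radius 2 px, disk, per axial slice | "2 pixels (4.0 mm)" is an in-plane statement at 2 mm pixels; with 4 mm slices an isotropic 3-D erosion would be a different operation, so 2-D per slice is the default and `full_3d` an option |
| aggregation | `summed` | see below |
| reproducibility SD | sample (n−1) | the natural estimator for a handful of repeats |

### Two readings of the fat-fraction ratio

"The ratio of the water and fat signal intensities within the eroded ROI"
can mean the ratio of summed intensities or the mean per-voxel ratio. The
two agree exactly when proton density is uniform over the ROI and diverge
otherwise; the summed form is signal-weighted and robust to near-zero
voxels, so it is the default, `voxel_mean` is selectable, and every result
records which was used. Voxels with zero total signal are excluded from
`voxel_mean` and counted in the result rather than silently dropped.

### What is eroded and what is not

Erosion exists to keep boundary partial-volume fat (subcutaneous fat around
the compartment, seam fat around individual muscles) out of the intensity
ratios. It is therefore applied to the compartment mask (for IMAT) and to
each muscle mask (for IntraMF), but **not** to the subcutaneous mask and
**not** to the volumes entering SF/M: volumetry has no edge-effect problem,
and eroding it would bias both numerator and denominator. An eroded ROI
that comes back empty is an error (the ratio would be undefined); a
non-empty mask whose individual slice empties produces a warning naming the
slice.

## The synthetic cohort as study conditions

`cohortSpec()` defaults encode the emulated study: 10 BSCP subjects (GMFCS
I/II/III in counts 2/5/3) and 10 controls; per-muscle true fat fractions
drawn from truncated normals with control means of 4–5 %, a +10
percentage-point BSCP shift and a 3-point between-subject SD; a GMFCS
gradient of −2/0/+3 points so level III is most affected; subcutaneous ring
thickness 8 vs 13 mm, which with the default geometry puts the expected
SF/M ratio near 1.9× the control value; anthropometrics drawn from the
target study's group summaries (mass 64.0 ± 11.5 vs 71.2 ± 11.8 kg, etc.);
and Rician channel noise at σ = 2 on s₀ = 100 (SNR 50). These are chosen
once as the simulated study conditions, not tuned per analysis.

What the generator deliberately does **not** emulate: anatomical shape
variation (the leg is an extruded stylised cross-section), partial-volume
mixing at tissue boundaries (labels are crisp), T2* decay, eddy-current
phase errors, multi-peak fat spectra, coil-sensitivity shading, motion, and
between-visit repositioning. Passing tests therefore demonstrate that the
measurement chain is correct and calibrated under its own signal model —
not that it is robust to every artefact of real acquisitions. The T1-bias
and noise-bias confounders are *simulated* so their directional effects can
be verified (both inflate apparent fat), but no correction is attempted.

## Numerical choices

* **Erosion** is an exact binary min-filter: a voxel survives iff every
  structuring-element offset lands on a mask voxel, with outside-the-grid
  treated as background. The disk element is $\{(dx,dy): dx^2+dy^2 \le
  r^2\}$. The implementation intersects shifted copies of the mask, which
  is algebraically identical and vectorised over the volume; the test suite
  pins it against an independent per-pixel brute-force oracle and against
  `EBImage::erode` with the same kernel (noting EBImage replicates edges,
  so the comparison keeps a background border).
* **Gaussian channel noise is clipped at zero.** Channel intensities are
  magnitudes and the container enforces nonnegativity; the clip affects
  only near-zero-signal voxels. Rician noise (the honest magnitude model)
  needs no clip. The Monte-Carlo reproducibility reference uses the same
  model on both sides of the comparison.
* **Field-map estimation** searches $\psi$ on a grid over $\pm 1/(2\Delta
  TE)$ (the unaliased range, ±500 Hz at ΔTE = 1 ms). The single-peak model
  admits a swap-equivalent residual minimum about one chemical shift away
  (434 Hz at 3 T); the estimator refines the two best-separated minima per
  voxel and, when their residuals are indistinguishable, prefers the
  smaller $|\psi|$ — physiologic shim offsets are small against the
  chemical shift. A 3×3 in-plane median filter then suppresses isolated
  swaps, and a final bounded refinement (±25 Hz, wide enough to undo
  median-induced edge shifts, far below the swap separation) restores
  per-voxel accuracy. With the field supplied the solve is a single linear
  least squares, exact on noiseless data.
* **Type II sums of squares** for the two-way ANOVA are computed by
  explicit model comparison (residual-SS difference between the reduced and
  full additive models), which remains defined when the residual is exactly
  zero; it is cross-checked against `car::Anova` on noisy unbalanced data.
* **Median test**: values equal to the grand median fall in the "≤ median"
  cell (recorded in the report); the dichotomised 2×2 table is tested with
  Fisher's exact test below a total n of 40 — at the 20-subject study scale
  the chi-square approximation is not trustworthy — and chi-square above.
* **Ties and degenerate inputs** are flagged, not guessed: constant groups
  make normality and Kruskal–Wallis undefined (`undefined = TRUE` in the
  record), zero-variance columns flag their correlations, an all-zero ROI
  is an error.

## Design choices where the design was open

* **One-way vs two-way ANOVA.** The battery's default analyses IntraMF
  with GMFCS level and muscle identity as additive fixed factors (Type II),
  since group-level contrasts are usually reported alongside a per-muscle
  structure; a one-way GMFCS-only form is always computed too, because the
  two summaries answer slightly different questions and published analyses
  of this design have used both. Both appear in every report; the package
  does not guess which a reader wants.
* **ANOVA population.** GMFCS is defined only for the affected group, so
  the ANOVA runs on BSCP subjects; the control group enters through the
  two-group t-tests, median tests and correlations instead.
* **Multiple testing.** No correction by default — the emulated analysis
  style tests each variable at p ≤ 0.05 — with a Holm option (`holm =
  TRUE`) for the correlation families.
* **Bone.** The phantom excludes bone (and a small clearance ring) from
  the compartment and muscle ROIs; whether a manual compartment ROI would
  include marrow is operator-dependent, and excluding it keeps the
  ground-truth fat fraction of the compartment well defined.
* **Pooled vs Welch t.** Pooled-variance Student t is primary (variance
  equality is checked by Levene's test first); Welch is a flag. The
  summary-statistic form exists so published group tables can be checked
  without subject-level data.
* **Repeat scans** model acquisition noise only: each repeat redraws noise
  on identical anatomy. Between-visit repositioning variance is *not*
  modelled, so the simulated reproducibility is acquisition-level.

## Problem sizes used by the tests and the acceptance script

Unit and property tests run on 48 × 48 grids with a 40 mm leg radius
(geometry scaled with the grid so ROIs stay several erosion radii thick).
The Monte-Carlo calibrations — the 1000-draw reproducibility reference band
(on a 32 × 32 × 4 phantom), the 20-seed power check and the 200-seed
type-I-error check (48 × 48 × 8 cohorts of 10+10 subjects) — keep the
study-condition parameters and scale only the grid; these sizes are the
package's chosen desk-scale operating point and are stated here so results
are interpreted at that scale. The full-geometry default (64 × 64 × 27) is
used for the closed-loop and confounder checks, where a single phantom
suffices.

## Worked example

```{r example}
# a small two-group cohort, simulated, quantified, tested
spec <- cohortSpec(gridShape = c(48L, 48L, 8L), outerRadiusMm = 40,
                   sfThicknessMeanMm = c(TD = 6, BSCP = 9),
                   sfThicknessSDMm = c(TD = 1.5, BSCP = 2.5))
sim <- simulateCohort(spec, seed = 11)
cohort <- quantifyCohort(sim)
aggregate(cbind(intramf_mean, imat, sf_m) ~ group, cohort, mean)

report <- runStatsBattery(cohort)
report$anovaTwoWay$effects$gmfcs$p     # GMFCS main effect on IntraMF
report$medianTests$imat$p              # IMAT between groups
report$physical$mass_kg$ttest$p        # body mass between groups
```

The BSCP rows sit ~10 percentage points above the controls in mean IntraMF
by construction; IMAT exceeds every IntraMF because the compartment ROI
contains the fatty seams; SF/M is higher in the affected group but, with
these variances and n = 10 + 10, usually not significantly so.

## Known limitations

* Single-peak fat model throughout; absolute fat fractions from multi-peak
  reconstructions will differ.
* The field-map estimator is a per-voxel search plus median smoothing — a
  fidelity stand-in validated on synthetic data, not a clinically robust
  region-growing algorithm; with strong noise and steep field gradients it
  can still swap.
* Gaussian-noise clipping slightly biases near-zero channels; use the
  Rician model when the bias itself is under study.
* The phantom's crisp labels mean partial-volume effects — a real driver of
  the T1 bias discussed above — are represented only through the explicit
  β parameter, not emergent mixing.
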