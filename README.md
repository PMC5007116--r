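# rpmpet

Reference-region kinetic quantification for dynamic TSPO PET, with a
synthetic-data generator that lets the whole chain be exercised and
validated without access to scan data.

## The problem

First-generation TSPO tracers such as (R)-[11C]PK11195 are used to image
microglial activation, but they have no anatomical reference region: TSPO
is expressed throughout the brain. The standard quantification chain is

1. **SVCA4** — supervised cluster analysis with four kinetic classes (gray
   matter with specific binding, gray matter without specific binding,
   white matter, blood). Each in-brain voxel's time-activity curve (TAC)
   is normalized to unit area and decomposed by non-negative least squares
   into four predefined class templates; the voxels loading most on the
   gray-without-specific-binding class supply the reference input curve.
2. **RPM-Vb** — a basis-function implementation of the simplified
   reference tissue model (SRTM) with a vascular correction. For each
   washout rate `θ3` on a logarithmic grid, the voxel TAC is fit by the
   weighted linear model

   ```
   C_T(t) ≈ θ1·Cr(t) + θ2·(Cr ⊗ e^{−θ3 t})(t) + θv·Cb(t)
   ```

   and the best grid point is kept. The reported parameters are
   `R1 = θ1`, `k2 = θ2 + θ1·θ3`, `Vb = θv`, and the outcome measure
   `BP_ND = k2/θ3 − 1`, the non-displaceable binding potential.
3. **ROI aggregation** — volume-weighted composite regions (total gray
   matter; frontal, temporal, parietal cortex; striatum; thalamus) from a
   label volume.
4. **Group statistics** — one-way ANOVA, age-adjusted ANCOVA, Wilks MANOVA
   over the regional ROIs, Levene's variance test, Pearson correlations,
   the gender chi-square, Bonferroni correction, and the classical
   normal-approximation two-group sample-size formula

   ```
   n = ⌈ (z_{1−α/2} + z_{power})² (σ1² + σ2²) / (μ1 − μ2)² ⌉.
   ```

Because the package targets studies whose scans are not public, it also
ships the simulator used to validate all of this: a tri-exponential bolus
input, an analytic two-tissue-compartment forward model, frame averaging
over a 22-frame / 60.5-min acquisition, a count-statistics noise
surrogate, 4D dynamic phantoms with ground-truth maps, and a two-group
cohort generator whose BP_ND and demographic distributions emulate a
17-control / 19-patient recent-onset psychosis study.

## Worked example

```r
library(rpmpet)

res <- run_pipeline(pipeline_config(seed = 42))
subset(res$report, test == "anova_group",
       select = c(roi, statistic, p, p_bonferroni))
```

```
# A tibble: 6 × 4
  roi        statistic      p p_bonferroni
  <chr>          <dbl>  <dbl>        <dbl>
1 total_gray     0.418 0.522         0.522
2 frontal        2.86  0.0998        0.499
3 temporal       0.122 0.729         1
4 parietal       0.281 0.599         1
5 striatum       0.572 0.455         1
6 thalamus       1.72  0.198         0.989
```

The run simulates the cohort, extracts the SVCA4 reference from a noisy
phantom, synthesizes and fits every subject's ROI TACs with RPM-Vb, and
tests the fitted BP_ND group differences: at the emulated effect sizes
(e.g. total gray matter 0.14 ± 0.09 vs 0.17 ± 0.09) none of the ROI
comparisons reaches significance, which is exactly what the power
calculation predicts for groups of this size:

```r
sample_size_two_groups(0.07, 0.18, 0.10, 0.08, alpha = 0.01, power = 0.80)$n
#> [1] 16
```

Voxelwise maps work the same way on image data:

```r
ph  <- make_phantom(phantom_spec(alpha = 0.3, seed = 1))  # 32x32x16 phantom
tm  <- make_class_templates()
ref <- extract_reference(ph, tm)                           # SVCA4
maps <- parametric_map(ph, ref$reference_tac,
                       blood = frame_average(whole_blood(
                         input_function_params(), seq(0, 3630.5, 0.5)),
                         default_frame_schedule()))
median(maps$bp_nd[ph$class_map == 1], na.rm = TRUE)
#> [1] 0.4915756   # ground truth 0.5
```

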