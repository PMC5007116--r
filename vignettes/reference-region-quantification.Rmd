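---
title: "Reference-region quantification of dynamic TSPO PET: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-region quantification of dynamic TSPO PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpmpet)
```

## Scope

`rpmpet` implements the quantification chain used for first-generation
TSPO tracers that lack an anatomical reference region: supervised-cluster
reference extraction (SVCA4), basis-function SRTM fitting with a vascular
correction (RPM-Vb), composite-ROI aggregation, and the group-comparison
and power statistics of a two-group study. Because such studies' raw scans
are typically not shareable, the package includes the full simulator used
to validate every stage. This vignette records the models, the tunable
parameters, and the design decisions, so that a user knows exactly what a
passing test suite does — and does not — demonstrate.

## Forward models

**Input function.** The arterial input is the standard tri-exponential
bolus form
$$C_p(\tau) = (A_1\tau - A_2 - A_3)e^{-\lambda_1\tau}
  + A_2 e^{-\lambda_2\tau} + A_3 e^{-\lambda_3\tau},
  \qquad \tau = t - t_\text{delay},$$
zero before bolus arrival and clipped at zero. The defaults
($A_1 = 300$ kBq/mL/min, $A_2 = 1.5$, $A_3 = 0.8$ kBq/mL,
$\lambda = 4, 0.25, 0.012$ min$^{-1}$, delay 0.5 min) give a realistic
~29 kBq/mL peak shortly after injection and a sub-kBq/mL tail at 60 min.
They are simulator conventions, not measured values, and are fully
configurable. The whole-blood curve is taken equal to the plasma curve —
no metabolite or plasma/whole-blood partitioning is modelled, consistent
with the package's scope (decay-corrected, reconstruction-corrected
images in, no plasma modelling of real data).

**Tissue.** Ground-truth tissue kinetics follow the two-tissue
compartment model (rates per minute)
$$\dot C_1 = K_1 C_p - (k_{2t}+k_3)C_1 + k_4 C_2,\qquad
  \dot C_2 = k_3 C_1 - k_4 C_2,$$
$$C_T = (1-v_b)(C_1+C_2) + v_b C_b .$$
The solution uses the analytic bi-exponential impulse response
(eigen-decomposition of the $2\times2$ rate matrix) rather than ODE
stepping; a fine-step Runge–Kutta solver appears only as a test oracle.
All convolutions run on a fine internal grid (default 0.5 s) with an
*exact piecewise-linear* scheme: the integral of a linear segment against
the exponential kernel is evaluated in closed form and accumulated by a
one-pass recursion. Accuracy is therefore independent of the frame
schedule, and the scheme is exact for the interpolants it is given.

**Acquisition.** The default schedule is 22 frames over 3630 s
(1×30, 6×5, 3×10, 4×60, 2×150, 2×300, 4×600 s): short frames bracket the
bolus, long frames the washout. Only the total duration of the emulated
protocol is fixed by the study design; the frame split is a package
convention and is configurable. Frame values are means over the frame
interval (adaptive quadrature for functional inputs; exact
piecewise-linear integration for sampled curves), reported at frame
mid-times.

**Noise.** Simulated TACs are decay-corrected, as reconstructed PET data
are; physical decay therefore enters only the noise model. Per-frame
Gaussian noise has
$$\sigma_j = \alpha\sqrt{\frac{\max(C_j,0)}{\Delta t_j\, 2^{-t_j/T_{1/2}}}},$$
with $\Delta t_j$ the frame duration in seconds and $T_{1/2} = 20.4$ min
(C-11). Gaussian rather than Poisson noise is the standard surrogate for
reconstructed-image noise and keeps the linear fits well-posed. The level
$\alpha$ is unitless; $\alpha = 0.3$ is used as the voxel-level reference
condition and $\alpha = 0.1$ for ROI-averaged curves, which are far less
noisy than single voxels. All stochastic operations take explicit seeds
and restore the caller's RNG state: the same seed reproduces the same
data bit for bit.

## The four kinetic classes

SVCA4 needs templates for gray matter with specific binding, gray matter
without specific binding, white matter, and blood. Defaults:

| class | K1 | k2t | k3 | k4 | vb | BP$_{ND}$ |
|---|---|---|---|---|---|---|
| gray, specific binding | 0.30 | 0.15 | 0.15 | 0.30 | 0.05 | 0.5 |
| gray, no specific binding | 0.30 | 0.15 | 0 | — | 0.05 | 0 |
| white matter | 0.15 | 0.08 | 0 | — | 0.03 | 0 |
| blood | — | — | — | — | 1 | — |

The two gray classes share delivery and efflux, so the specific class has
$R_1 = 1$ and reference-relative $k_2 = 0.15$ min$^{-1}$ — the regime the
SRTM is built for. The binding exchange is deliberately fast
($k_3/k_4 = 0.15/0.30$) so that the specific class behaves as an
effective one-tissue system over the hour-long scan and sits inside the
SRTM's validity domain; with much slower exchange the SRTM itself becomes
the dominant error source, which is a property of the model, not of this
implementation. Templates are frame-averaged and normalized to unit
trapezoid area, so the decomposition compares curve shape, not amplitude;
the four templates are verified to be linearly independent at
construction.

Real-data use would supply population templates from a TSV; deriving such
templates from scans is out of scope.

## SVCA4 reference extraction

Within the anatomical mask, each voxel TAC is unit-area normalized
(voxels with non-positive area are excluded and counted) and decomposed
by non-negative least squares (`pracma::lsqnonneg`) into the four
templates — weights are mixture proportions, hence the non-negativity
constraint; an unconstrained variant exists for comparison. Voxels are
ranked by their class-2 (gray-without-specific-binding) weight. The
default selection keeps the top 10% of in-mask voxels (at least 50) and
averages their **raw** TACs weighted by the class-2 weights; a hard
weight threshold is available instead. Neither the selection fraction nor
the weighting scheme of the original SVCA literature is fully
standardized, so both are exposed and these defaults are documented
choices. Weight-based soft averaging degrades gracefully with noise;
tightening the fraction monotonically improves fidelity on noiseless
phantoms (a tested property).

## RPM-Vb fitting

For washout rates $\theta_3$ on a logarithmically spaced grid (default 64
points in $[0.006, 0.6]$ min$^{-1}$, bracketing $k_2/(1+BP_{ND})$ for
plausible first-generation TSPO kinetics), the basis curves
$B_{\theta_3} = C_r \otimes e^{-\theta_3 t}$ are precomputed by fine-grid
convolution of the measured reference curve and frame-averaged. Each
target TAC is then fit by weighted linear least squares,
$$C_T \approx \theta_1 C_r + \theta_2 B_{\theta_3} + \theta_v C_b,$$
and the grid point with minimal weighted residual sum of squares wins
(ties break to the smallest $\theta_3$, deterministically). Default frame
weights are proportional to duration × decay; uniform weights are
selectable. Degenerate all-zero voxels are flagged rather than fit, and a
grid-endpoint optimum is flagged as `boundary`.

Parameter conventions, a genuinely open design point:

* Default: $R_1 = \theta_1$, $k_2 = \theta_2 + \theta_1\theta_3$,
  $V_b = \theta_v$ clamped to $[0,1)$, $BP_{ND} = k_2/\theta_3 - 1$. When
  a target truly follows $(1-v_b)\,\mathrm{SRTM} + v_b C_b$, this
  convention shrinks $BP_{ND}$ by $v_b(1+BP_{ND})$ — about 0.075 at
  $BP_{ND}=0.5$, $v_b=0.05$ — which stays within one $\theta_3$ grid step.
  `rescale_vb = TRUE` divides $\theta_1, \theta_2$ by $(1-V_b)$ and
  removes the shrinkage.
* In practice the shrinkage is smaller than this worst case: an extracted
  reference region carries its own blood fraction, so the net blood
  signal the $\theta_v$ column absorbs is the *excess* over the
  reference's, and on phantoms where target and reference share $v_b$
  the fitted maps recover truth within ~0.01 with either convention.
* Negative $BP_{ND}$ estimates are retained. Clipping at zero would bias
  group means upward exactly where TSPO group means live (near zero).

ROI values can be produced two ways: the mean of the voxelwise map over
the ROI (default, matching the parametric-mapping emphasis), or a single
fit of the ROI-averaged TAC. Both are implemented; the package does not
claim either is "the" original choice.

## ROI aggregation and statistics

Composite ROIs are volume-weighted averages of labelled subregions (e.g.
the frontal cortex from its seven constituent cortical labels), with NA
voxels excluded together with their volume share.

The statistical battery mirrors a two-group neuroimaging analysis: group
ANOVA per ROI, the age-adjusted ANCOVA group term (type III, via `car`),
Wilks' $\Lambda$ MANOVA across the five regional ROIs with age entered
before group (so the group effect is covariate-adjusted), mean-centered
Levene tests (the median-centered Brown–Forsythe variant sits behind a
flag), Pearson correlations, the gender $\chi^2$ **without** continuity
correction (the convention that reproduces the emulated table's printed
0.02; Yates would give ≈ 0), and Bonferroni adjustment with $m = 5$ over
the regional ROIs — total gray matter is the primary outcome and is
reported unadjusted. The "ROI as within-subject factor" multivariate test
is parameterized as Wilks' $\Lambda$ on the 5-column response matrix;
that reading is a documented choice. All group tests are two-sided.

The sample-size routine uses the classical normal-approximation planning
formula
$$n = \left\lceil \frac{(z_{1-\alpha/2}+z_{\text{power}})^2
  (\sigma_1^2+\sigma_2^2)}{(\mu_1-\mu_2)^2} \right\rceil,$$
deliberately **not** the noncentral-$t$ version: the normal approximation
is the formula whose answer (16 per group at
$\mu_1=0.07,\ \mu_2=0.18,\ \sigma_1=0.10,\ \sigma_2=0.08,\ \alpha=0.01$,
power 0.80) the emulated study reports; noncentral-$t$ gives ≈ 18. The
returned object also carries the achieved power at the integer $n$.

## The synthetic cohort

`cohort_spec()` defaults encode the emulated study's margins: 17 controls
vs 19 patients; age 26 ± 4 years clipped to 20–34 in both groups; gender
14/3 and 16/3 sampled as fixed counts (not Bernoulli draws) so the
margins reproduce exactly; injected dose 433 ± 23 vs 407 ± 73 MBq,
specific activity 96 ± 28 vs 74 ± 19 GBq/µmol, injected mass 1.7 ± 0.6 vs
2.1 ± 0.6 µg; nicotine 5/12 vs 13/6 and cannabis 0/17 vs 4/15 as inert
covariate flags; PANSS totals (53 ± 10) for patients only. Per-ROI
BP$_{ND}$ is drawn from the group's normal distributions with a shared
subject factor giving inter-ROI correlation 0.8 — global TSPO expression
varies strongly between subjects, so regional values within a subject
move together; the printed tables do not constrain this correlation, so
it is a free, documented simulator parameter. Negative BP$_{ND}$ draws
are allowed by default (the group SDs imply near-zero mass, and
reference-tissue estimates can legitimately be slightly negative).

The default phantom is a 32 × 32 × 16 volume of 2 mm isotropic voxels:
an ellipsoidal brain with a white-matter core, a gray shell, a lateral
specific-binding region, and ~3% scattered blood voxels — desk-scale, but
with a genuine mask/background distinction for the SVCA masking step and
enough class-2 voxels that the top-10% selection is meaningful.

## Problem sizes and what the tests show

The validation suite runs, among others: exact-identity checks (SRTM
self-fit; bit-for-bit reproduction of the reference at $R_1=1$,
$BP_{ND}=0$); oracle equivalences against independent brute-force
implementations (support-enumeration NNLS, hand-computed ANOVA sums of
squares, closed-form $\chi^2$, determinant-ratio Wilks $\Lambda$,
trapezoid-sum convolution, fixed-step Runge–Kutta for the two-tissue
system); noiseless phantom recovery (reference within machine precision,
$BP_{ND}$ maps within 0.02 median absolute error); selection precision
≥ 0.9 at voxel noise $\alpha = 0.3$; a 3 × 3 recovery grid over
$BP_{ND} \in \{0, 0.15, 0.5\}$ × $\alpha \in \{0, 0.1, 0.3\}$ with 100
replicates per noisy cell; and a 1000-replicate null calibration of the
full ROI-level pipeline (equal group means, simulate → extract → fit →
test), whose rejection rate must sit in 3–7% at $\alpha = 0.05$. These
sizes keep the whole suite within a few minutes on one CPU.

What passing does **not** show: the simulator draws subject BP$_{ND}$
directly from group normal distributions — it does not model
scanner-specific noise correlations, motion, partial-volume effects,
reconstruction artefacts, co-registration or segmentation error, or any
biological structure beyond the configured means, SDs, and inter-ROI
correlation. Agreement on synthetic data validates the *computations*,
not the acquisition-side assumptions of any real study.

## Known limitations

* The SRTM assumes effectively one-tissue kinetics in target and
  reference; targets with slow specific-binding exchange acquire a model
  bias no implementation can remove.
* The basis-function fit interpolates the measured (frame-averaged)
  reference curve piecewise-linearly onto the fine grid; with very coarse
  late frames this contributes a small (<2% here) systematic component.
* The vascular correction shares one blood curve across the volume; true
  regional blood differences fold into $\theta_v$.
* No spatial regularization is applied to parametric maps, and no
  partial-volume correction anywhere, by design.
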