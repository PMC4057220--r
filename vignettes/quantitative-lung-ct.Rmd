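---
title: "Quantitative thoracic CT analysis with lungqct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative thoracic CT analysis with lungqct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungqct)
```

## The voxel model

CT attenuation in the lung is well approximated as a two-component mixture:
gas at -1000 Hounsfield units (HU) and parenchymal tissue at water-like
density (0 HU). A voxel's CT number then fixes its composition,

$$\frac{\mathrm{CT}}{-1000} \;=\; \frac{V_{gas}}{V_{gas}+V_{tissue}},$$

so for any region of interest

$$V_{gas} = \frac{\mathrm{CT}}{-1000}\,V_{total}, \qquad
  V_{tissue} = \Bigl(1-\frac{\mathrm{CT}}{-1000}\Bigr)\,V_{total}.$$

Tissue density is fixed at 1 g/ml, so tissue mass in grams equals tissue
volume in ml; `summarize_voxels()` applies these formulas voxel by voxel
and aggregates. Two consequences are worth keeping in mind:

* the decomposition is *literal* by default — a voxel above 0 HU gets a
  (slightly) negative gas fraction. This reproduces the model exactly;
  `mode = "clamped"` truncates gas fractions to [0, 1] for use with dense
  pathology or residual contrast. The two modes agree whenever all voxels
  lie at or below 0 HU.
* voxels outside [-1000, +100] HU are *included*, evaluated literally, and
  tallied (`n_out_of_range`). Manual lung contours are assumed to exclude
  bone and contrast; the tally makes violations visible without silently
  editing the data.

### Aeration compartments

Parenchyma is classified by density into four compartments, at the integer
HU ranges conventional in the quantitative-CT literature: noninflated
(+100 to -100), poorly inflated (-101 to -500), well inflated (-501 to
-900), overinflated (-901 to -1000). The cut points are implemented as
half-open real intervals at -900 / -500 / -100 so that every integer HU
value lands exactly where the integer ranges place it (e.g. -900 HU is
well inflated, -901 HU overinflated). `compartment_summary()` reports both
**mass fractions** (share of regional tissue mass — the convention behind
headline "percent of lung weight" numbers) and **volume fractions** (share
of regional volume — the convention of attenuation histograms); the two
differ strongly because aerated voxels carry little mass. The
low-attenuation volume below -950 HU (`low_attenuation_volume_fraction()`)
is the standard emphysema index.

## Regional analysis and superimposed pressure

`build_regional_grid()` cuts each lung into 10 apex–base sections of equal
physical height, and each section into 10 sterno-vertebral levels of equal
height between that section's own ventral-most and dorsal-most extent
(level 1 most ventral). Extents are physical (voxel edges included) and
computed per lung and per section, so the partition is robust to
anisotropic spacing and to lungs whose ventral–dorsal depth varies from
apex to base. Voxel centres on a bin edge go to the more dorsal / more
basal bin — an explicit tie rule so the partition is exhaustive and
deterministic. `merge_regions()` merges same-numbered elements (levels for
the sterno-vertebral axis, sections for the apex–base axis) and summarizes
each merged region; additive quantities sum exactly to the whole-lung
values because the regions partition the mask.

Treating the lung as a fluid, the pressure superimposed on a level is the
weight of the parenchyma above it. With level densities $\rho_k$ (tissue
mass over total volume, g/ml) and heights $h_k$ (cm),

$$P^{dorsal}_k=\sum_{j\le k}\rho_j h_j,\qquad
  P^{mid}_k=\sum_{j<k}\rho_j h_j+\tfrac{1}{2}\rho_k h_k ,$$

in cmH2O (1 g/cm³ × 1 cm ≡ 1 cmH2O). For a uniform column of density
$\rho$ and height $H$ the dorsal-most pressure is $\rho H$ — the one-line
column-weight formula — and the average over level midpoints is
$\rho H/2$.

Design choices that were genuinely open:

* **Averaging convention.** "Average superimposed pressure" is the
  unweighted arithmetic mean of the 10 midpoint pressures (zero-height
  levels excluded). A tissue-weighted average is also computed and exposed
  as an attribute; on gradient phantoms it is higher, since denser dorsal
  levels see more pressure. The unweighted mean is the default because it
  makes the uniform case exactly $\rho H/2$.
* **Merged-level heights.** When sections have different depths, the
  merged level $k$ spans different physical heights in different sections.
  Each voxel inherits its section's level height and the merged level's
  height is the mean over its voxels. This is exact for box-like masks and
  agrees with a brute-force per-voxel column integration within 5% on
  64³ gradient phantoms (oracle-tested).
* **BSA.** Regional volumes are normalized by the Du Bois body surface
  area, $0.007184\,w^{0.425}\,h_{cm}^{0.725}$ — the default choice where
  no formula is mandated.

## Normative references

`predict_reference_volume()` evaluates six published TLC/FRC reference
equations. The source table prints them without unit conventions, and some
are internally inconsistent as printed (the Cordero male formula yields
>16 L with height in metres *or* centimetres). Each registry entry
therefore carries an explicit convention chosen so that outputs are
physiologic, flagged in the registry rather than silently "fixed": Cordero
male takes height in inches, Cordero female in centimetres, Roca in
centimetres with output in ml (its female row is printed identically to
the male row, implemented as printed), the others in metres with output in
litres. A sanity test gates every equation to a physiologic volume at the
reference-population mean anthropometrics (2–9 L for TLC; 1.5–9 L for FRC,
since a supine FRC for a 1.6 m female is ~1.8 L).

`lung_regressions()` registers the linear fits of the 100-subject
normative cohort (lung weight on height and age, supine TLC on height,
sitting-TLC cross-prediction, the Bland–Altman trend, and the
poorly-inflated-tissue fits) with their published coefficients and r².
`predict_regression()` warns — but does not refuse — outside a documented
plausibility window, because such fits are routinely extrapolated.
`predicted_aeration_state()` converts a predicted gas volume plus a
measured tissue mass into the implied gas/tissue ratio and mean CT number,
$\mathrm{CT} = -1000\,G/(G+T)$.

## Cohort statistics

`fit_linear_regression()` (OLS with 2.5–97.5% t-based intervals),
`compare_groups()` (pooled-variance Student's t by default — the
convention of the reference analysis — with Welch as an option, since
male/female variances often differ) and `bland_altman()` wrap the standard
machinery behind a stable result schema. Bland–Altman dispersion is
reported **both** as mean ± 1 SD (the convention used in the reference
analysis' agreement figure) and as the conventional mean ± 1.96 SD limits
of agreement, labelled distinctly. No multiple-testing correction is
applied anywhere, matching the reference analysis; `cohort_summary()`
reports per-variable p-values as-is.

## What the synthetic data emulate — and what they do not

Real thoracic CT of this kind is not publicly deposited, so validation
rests on two generators whose ground truth is known analytically.

**Phantoms** (`generate_phantom()`): two ellipsoidal lungs on a regular
grid (defaults: 64³ voxels at 2 mm), with a uniform field, a linear
ventral–dorsal density gradient (the gravitational gradient of a supine
lung), or a four-compartment *mixture* field in which voxels take
band-interior anchor values (-950, -700, -300, -50 HU) apportioned by
largest remainder so the tissue mass splits across compartments at
requested percentages — making round-trip mass fractions exact up to
integer apportionment (<0.01% at 64³). Ground truth (ellipsoid volumes
$\tfrac43\pi abc$, field means, achieved mixture) is computed from the
specification, never from the voxelization, so voxelization error is
measurable: ≤2% volume error at 64³, shrinking with resolution
(convergence-tested at 32³/64³/128³). Phantoms have no airways, vessels,
fissures, partial-volume blur or scanner noise beyond optional Gaussian
jitter; passing phantom tests validates the *arithmetic* of the pipeline,
not segmentation or acquisition robustness on clinical scans.

**Cohorts** (`generate_cohort()`): per-sex normal anthropometrics at the
reference-population means/SDs (53 male / 47 female at n = 100; male
height 1.7 ± 0.1 m, female 1.6 ± 0.1 m), lung weight and supine TLC
generated from the registered height regressions plus Gaussian noise, and
compartment percentages drawn around the reference means (well-inflated
taken as the complement so percentages sum to 100). Two calibration
details matter:

* the noise SD comes from inverting the population r² relation,
  $s_e=|b|\,s_x\sqrt{(1-r^2)/r^2}$ (`calibrate_noise_sd()`), evaluated at
  the **analytic mixed-sex height SD** (≈0.112 m), not the within-sex
  0.1 m — the published fits pool the sexes, and using the within-sex SD
  would make simulated r² overshoot the target by ~0.06;
* responses are left exactly linear-plus-Gaussian. Resampling the rare
  negative response draw (probability ~0.3% at 1.6 m for supine TLC)
  truncates the noise asymmetrically across heights and measurably biases
  the recovered slope — a defect the parameter-recovery tests catch.
  Negative *anthropometric* draws are resampled (and counted), since
  heights and weights feed nonlinear downstream formulas.

Generated subjects satisfy the densitometric identities exactly
(total = gas + weight at 1 g/ml; mean HU = -1000·gas/total), so the cohort
generator doubles as an oracle for the table machinery. The printed
reference compartment mixture sums to 101% from rounding; where a
realizable mixture is needed the one-point excess is spread equally across
the four compartments (-0.25 each), keeping every compartment within
rounding of its printed value.

## Problem sizes and numerical choices

Validation simulations use 200 replicate cohorts of n = 100 (matching the
reference cohort size) for parameter recovery, and 64³ phantoms for
densitometry and pressure checks — sizes at which Monte-Carlo and
voxelization error are both well below the tolerances being tested while
the whole suite runs in about a minute and a half. Volume conservation and
partition additivity are asserted at 1e-9 relative tolerance (pure
floating-point error); recovery checks use Monte-Carlo standard errors
(3 SE in the 200-replicate end-to-end checks, 4 SE in the smaller
fixed-seed unit check, whose single realization makes a 3 SE bound fire
~1% of the time under the null); the 10-level pressure discretization is
held to 5% of a per-voxel oracle. All randomness flows through explicit
seeds (`withr::with_seed`), so every simulation is bit-reproducible.

## Known limitations

* The axis convention (x left–right, y ventral–dorsal, z apex–base,
  supine) is asserted, not inferred; NIfTI inputs in other orientations
  must be reoriented first.
* Lung segmentation is out of scope: masks are inputs, and the 1 = right /
  2 = left label convention is this package's own (the `--swap-lungs` CLI
  flag guards against reversed conventions).
* The two-compartment model ignores blood/tissue density differences and
  reconstruction-kernel effects; compartment fractions from sharp vs
  smooth kernels are known to differ on real scans.
* Reference equations are reproduced as printed, including the suspect
  Roca female row; they are registry entries, not re-derived fits.
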