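---
title: "Radial fat-mapping and 1D SPM of multifidus fat infiltration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial fat-mapping and 1D SPM of multifidus fat infiltration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatmapr)
```

# The problem

Fatty infiltration (FI) of the lumbar multifidus — the deep paraspinal
muscle that segmentally stabilizes the spine — is a marker of muscle
degeneration in chronic low back pain (cLBP). Quantitative water-fat MRI
(e.g. IDEAL) yields a per-pixel fat fraction in percent; with manual
left/right multifidus segmentations and the approximate center of
rotation (CoR) of each motion segment as inputs, the question is *where*
in the muscle, along its deep-to-superficial axis, FI is elevated in
association with patient covariates such as symptom chronicity and
physical activity — and whether those associations survive adjustment
for age, sex, BMI, disc degeneration and pain severity.

`fatmapr` implements the full analysis chain: radial fat-mapping of
segmented slices into distance-normalized 1D profiles, one-dimensional
statistical parametric mapping (SPM) with random-field-theory (RFT)
cluster inference, depth-windowed scalar metrics, and the cohort-level
regression / mixed-effects stage. A synthetic cohort generator with
exactly known injected effects makes every stage testable end to end.

# Radial fat-mapping

For one muscle side on one axial slice, all in-mask pixels are binned by
Euclidean distance $d$ from the CoR into non-overlapping shells of width
2 pixels: shell $k$ holds pixels with
$r_\min + 2k \le d < r_\min + 2(k+1)$, where $r_\min$ is the minimum
in-mask distance. Binning starts at $r_\min$ rather than at the CoR
itself because the muscle does not touch the CoR; anchoring at the first
occupied radius keeps shell occupancy stable across subjects. Shells are
full distance annuli intersected with the mask (no angular sectoring),
and the 2-pixel increment is taken in acquisition-grid pixel units.

Each shell contributes its mean FI% placed at the shell's mid-depth.
Mid-depth is computed as the **mean radial distance of the shell's
pixels**, not the geometric bin center: for partially occupied shells the
pixel mean is the area-weighted location of the measurement, and it has
the useful exact property that any fat field affine in depth is
reproduced without bias — the per-shell means then lie exactly on the
generating line, so the interpolated curve matches it to floating-point
precision at interior grid nodes.

Depth is normalized to 0–100% of the radial muscle width
($r_\min$ to $r_\max$, per side and slice) and the per-shell means are
linearly interpolated onto a common 101-node grid (integer percent;
0% = deepest). Nodes beyond the first/last shell mid-depths take the
nearest shell's value — no extrapolation. Empty interior shells (mask
gaps) are bridged by interpolation with a warning. The four curves per
subject and lumbar level (left/right × 2 slices) are averaged node-wise
into one fat-map; normalization is per side *before* averaging, so each
side's own muscle width defines its depth axis.

Two scalar metrics accompany the curves:

* **overall FI%** — the pixel-weighted mean over all in-mask pixels of
  both sides and both slices;
* **deep15 FI%** — the mean of curve nodes 0..15 inclusive (16 nodes), a
  closed depth window covering the deepest 15% of the radial width
  measured from the CoR.

# The SPM engine

At every grid node $x$, the subject curves $y_i(x)$ are regressed by
ordinary least squares on a design with intercept, the covariate of
interest, and adjusters (default age, sex, BMI; sex as a female
indicator with male reference; continuous columns z-scored, which leaves
the t-field unchanged). The SPM{t} field is
$t(x) = \hat\beta(x)/\mathrm{SE}(\hat\beta(x))$ with
$\nu = n - p$ degrees of freedom.

**Smoothness.** The residual field's FWHM is estimated by the standard
lattice approach: residuals are normalized node-wise to unit sum of
squares, the per-node resel density is $\sqrt{v(x) / (4\log 2)}$ with
$v(x)$ the mean squared gradient of the normalized field (central
differences), and FWHM is the reciprocal of the mean density. Taking
gradients of the *normalized* field (rather than normalizing the raw
gradients) makes a rank-1, perfectly correlated residual field return
exactly the field length. Estimates are clipped to
[grid spacing, field length].

**Threshold.** The critical value solves
$$\mathrm{E}[\mathrm{EC}](t) \;=\; P(T_\nu > t) \;+\; R_1\,
\frac{\sqrt{4\log 2}}{2\pi}\Bigl(1 + \tfrac{t^2}{\nu}\Bigr)^{-(\nu-1)/2}
\;=\; \alpha^\*,$$
with $\alpha^\* = \alpha/2$ per tail for the two-tailed default. The
1D resel count is taken as $R_1 = \max(L - \mathrm{FWHM},\,0) /
\mathrm{FWHM}$ rather than the textbook $L/\mathrm{FWHM}$: the
correlation length already covered by the point-probability term is
excluded from the search volume. For rough fields
($L \gg \mathrm{FWHM}$) the two counts coincide to within one resel,
while in the fully smooth limit ($\mathrm{FWHM} = L$) the threshold
reduces *exactly* to the pointwise two-sided t quantile — the behaviour
one wants from a familywise threshold when the field carries only one
effective comparison. The empirical check that this controls error is
the package's familywise-error simulation: across 500 null cohorts
(n = 100, smooth noise of FWHM 10 grid-percent) the fraction with any
supra-threshold cluster must fall inside the binomial 95% band around
0.05; the test suite and the acceptance script both recompute it.

**Clusters.** Supra-threshold clusters are maximal same-sign runs of
nodes with $|t| > t^*$; endpoints are refined by linear interpolation of
the piecewise-linear t-field to the exact crossing, so non-integer
extents (e.g. a cluster from 85% to 94.6%) are expressible. Each cluster
carries an extent-based RFT p-value from the standard approximation: the
expected number of clusters $\mathrm{E}[m] = R_1\,\rho_1(t^*)$, the
expected suprathreshold occupancy, and an exponential-in-$k^2$ tail for
the cluster extent in resel units, combined as
$p = 1 - \exp(-\mathrm{E}[m]\,P(k \ge k_{obs}))$. This is an
approximation; the package's primary inferential claim (calibrated
familywise error of *detecting any* cluster) does not depend on it.

Two-tailed inference is the default because directional hypotheses were
not prespecified; one-tailed is available via `tails = 1`. Subjects with
missing covariates are dropped listwise with a logged count, and cohorts
under 20 subjects trigger a warning about RFT approximation quality.

# Cohort-level models

Three model structures operate on the scalar metrics:

1. `chronicity_regression()` — OLS of chronicity (years) on the
   per-subject mean FI metric (deep15 or overall), mean Pfirrmann grade,
   age, sex, BMI.
2. `activity_regression()` — OLS of weekly MET-minutes on chronicity,
   pain severity, age, sex, BMI.
3. `mixed_fi_model()` — REML linear mixed model of the level-specific
   metric on chronicity, level-specific disc degeneration, activity,
   pain, age, sex, BMI and lumbar level, with a per-subject random
   intercept (two rows per subject).

Continuous fixed effects in the mixed models are z-scored by default, so
estimates are FI% per SD and covariates on wildly different raw scales
(years vs thousands of MET-minutes) are comparable; the raw scale is
available with `standardize = FALSE`. P-values use Satterthwaite
degrees of freedom via `lmerTest`. A singular fit (random-intercept
variance estimated at zero) is reported as a legitimate boundary
estimate, not a convergence failure; genuine non-convergence under REML
triggers a flagged maximum-likelihood refit. Chronicity is modeled in
years throughout (it is collected in months; the SPM t-field is
invariant to that choice, scalar coefficients are simply rescaled).

Confidence-interval calibration is validated by simulation: for each of
the three structures, cohorts are generated with known coefficients and
the pooled 95% CI coverage over all generating coefficients across 200
replicates must lie in 93–97%. Coverage is pooled across a model's
coefficients because per-coefficient coverage at 200 replicates has a
binomial SD of ≈1.5%, making a ±2-point band needlessly noisy per term.

# The synthetic cohort generator

The generator is the study-conditions definition, not a tuning knob.

**Covariates.** Defaults reproduce a 223-subject cLBP cohort: pooled age
53.0 ± 15.4 yr, BMI 26.1 ± 4.4, pain 4.45 ± 1.9 NRS, chronicity
11.9 ± 12.7 yr, activity 3164.8 ± 2920.4 MET-min/wk, 54% female.
Chronicity is left-truncated at 0.25 yr (pain for at least three of the
past six months) and MET-minutes at 0. Naively parameterizing the
truncated normals by the reported mean/SD would inflate the realized
mean (truncation at 0.25 with location 11.9 and scale 12.7 yields a mean
near 15.9), so the location is calibrated by root-finding so the
*truncated* mean equals the reported mean. The realized SD is then
smaller than the reported SD; matching both moments is infeasible for
chronicity (the target coefficient of variation relative to the bound
exceeds the truncated-normal maximum of 1), so the mean — the quantity
the downstream models are anchored on — takes precedence. Pfirrmann
grades are drawn per level from a default distribution centred on grades
3–4, (0.05, 0.20, 0.35, 0.28, 0.12), a plausible lower-lumbar cLBP
profile; the paper's source cohort reports only mean disc degeneration,
so this is a package choice. Covariates are independent by default; a
Gaussian-copula correlation matrix can be supplied.

**Images.** Masks are half-annulus sectors posterior to the CoR
(radii 10–38 px on an 80×80 raster, ±15–75° about the posterior axis) —
deep-to-superficial geometry without anatomical modelling. Pixel spacing
defaults to 1 and is configurable. Pixel FI is a baseline radial profile
(default linear, 45% deep → 15% superficial, matching the deep-weighted
FI distribution of degenerated multifidus) evaluated at the pixel's
normalized depth, plus each active effect
(`sign × slope × z`-scored covariate, inside its depth window at its
level), plus iid Gaussian pixel noise (default SD 4 FI%), clipped to
[0, 100]. Left and right get independent noise; regeneration from the
same seed is bit-identical.

**Curve-level generator.** For statistical calibration studies the
rasters are unnecessary; `simulate_curve_cohort()` writes the same
structure directly onto the 101-node grid with *smooth* Gaussian noise —
white noise convolved with a Gaussian kernel of specified FWHM (default
10 grid-percent, the smoothness regime of fitted residual fields) and
unit marginal variance before scaling. This is the generator used for
familywise-error, threshold-vs-permutation and spatial-recovery
simulations.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real data: between-subject variability of the
baseline profile beyond covariate effects (real cohorts have substantial
biological curve variance; the image-level generator's only curve noise
is averaged pixel noise, which is why synthetic t-statistics can be very
large), anatomically realistic muscle shape, segmentation error and
rater disagreement, epimuscular fat handling, 3D volumes, and lumbar
lordosis differences between subjects. The validation demonstrates
statistical correctness of the machinery (calibration, recovery,
oracle equivalence), not clinical effect sizes.

# Numerical choices and degenerate inputs

* Interpolation of curves uses `approx(..., rule = 2)`: constant
  (nearest-shell) values beyond the outermost shell mid-depths.
* A mask whose pixels span a single distance shell yields a flat curve
  at that shell's mean, with a warning.
* A node-wise fit with numerically zero residual variance (interpolating
  response) warns and reports ±Inf t-values rather than failing.
* Rank-deficient designs fail fast, naming the collinear columns.
* FWHM estimates are clipped to [1, 100] grid-percent; an effectively
  perfectly correlated residual field returns the field length with a
  warning.
* One global seed is fanned out to stages and replicates as
  `(seed + 7919k) mod (2^31 - 1)`, keeping every child seed a valid
  32-bit integer and every artifact bit-reproducible.

# Validation problem sizes

The shipped validation uses: 500 null curve-cohorts of n = 100 for
familywise error; 10 smooth null cohorts of n = 50 against a
1000-permutation max-|t| oracle; 50 replicates of n = 223 with a
chronicity effect in the deepest 24% (slope 1.5 FI%/SD, noise 4 FI%) for
spatial recovery, scored by the Jaccard overlap of the best same-sign
cluster with the truth window; 50 random masks against brute-force
distance binning; and 200 replicates per regression structure for CI
coverage. These sizes give stable Monte-Carlo estimates (binomial SE
≈1% on the error rate) while keeping the full suite under a minute.

# Known limitations

* The CoR is a required input; the package does not estimate it from
  vertebral anatomy.
* Cluster p-values use the extent approximation described above and
  should be read as descriptive alongside the calibrated detection
  threshold.
* RFT assumes a smooth Gaussian residual field; for very small cohorts
  (< 20 subjects, warned) or very rough fields the threshold is
  approximate — the permutation oracle in the test suite is the
  benchmark there.
* The mixed models assume a random intercept only; level-specific
  random slopes are not supported (two levels give no leverage to
  estimate them).
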