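---
title: "Scanner-effect harmonization and its validation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanner-effect harmonization and its validation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative MRI features — regional volumes, cortical thickness, diffusion
metrics such as FA and MD — are not directly comparable across scanners.
Hardware, field strength and acquisition protocol leave a *scanner effect*
in the extracted numbers that can dwarf the biological signal of interest,
especially in longitudinal and multi-site studies. `scancombat` implements
the ComBat family of feature-level harmonization models together with a
travelling-subject validation framework: subjects scanned on several
scanners within a short interval provide a ground truth against which both
the size of the scanner effect and the cost of removing it can be measured.

A "scanner" throughout is the composite of site, machine model and
acquisition protocol (`make_scanner_id()`): two scans on the same magnet
with different sequences count as different scanners.

## The cross-sectional model

For feature $v$, scan $j$ on scanner $i$, the location-scale model is

$$y_{ijv} = \alpha_v + X_{ij}\beta_v + \gamma_{iv} + \delta_{iv}\,\varepsilon_{ijv},$$

with additive scanner offsets $\gamma_{iv}$, multiplicative scanner factors
$\delta_{iv}$, and covariates $X$ (age, sex, intracranial volume, time since
first scan by default; fully configurable). Fitting proceeds in the classic
three stages:

1. **Standardization** (`fit_standardization()`): per-feature OLS on
   mean-centered covariates plus scanner indicators under the weighted
   constraint $\sum_i n_i \hat\gamma_{iv} = 0$, so $\alpha_v$ is the grand
   covariate-adjusted mean. The pooled residual SD $\sigma_v$ uses divisor
   $N$; the within-scanner variance of the standardized data uses the
   unbiased $n_i - 1$ divisor. These conventions are part of the package's
   contract and make the worked examples exact.
2. **Empirical-Bayes shrinkage** (`estimate_hyperpriors()`, `eb_shrink()`):
   scanner effects are estimated once per feature, which is unstable when a
   scanner contributes few scans. Borrowing strength across features,
   $\hat\gamma_{iv}$ receives a normal prior and $\hat\delta^2_{iv}$ an
   inverse-gamma prior, both moment-matched across features per scanner.
   The parametric path iterates the conditional posterior means
   $$\gamma^*_{iv} = \frac{n_i\tau_i^2\hat\gamma_{iv} + \delta^{*2}_{iv}\bar\gamma_i}
        {n_i\tau_i^2 + \delta^{*2}_{iv}}, \qquad
     \delta^{*2}_{iv} = \frac{\theta_i + \tfrac12\sum_j (z_{ijv}-\gamma^*_{iv})^2}
        {n_i/2 + \lambda_i - 1}$$
   to a fixed point (tolerance $10^{-4}$ on the maximum absolute change,
   at most 1000 iterations; small problems converge in well under 50).
   The non-parametric path replaces the prior by the empirical distribution
   of the other features' estimates, weighting each candidate pair by the
   Gaussian likelihood of the feature's standardized data — each feature is
   excluded from its own candidate set to prevent self-reinforcement at
   small feature counts. `eb = FALSE` skips shrinkage entirely
   (location-shift model).
3. **Reconstruction**: $y^* = \sigma_v (z - \gamma^*_{iv})/\delta^*_{iv} +
   \alpha_v + X\beta_v$. Covariate relationships are preserved by
   construction.

## The longitudinal variant

`harmonize_longcombat()` replaces the OLS standardization with a per-feature
REML linear mixed model: scanner and covariates as fixed effects (same
weighted sum-to-zero constraint, recovered from the treatment-coded fit) and
a subject-specific random intercept, optionally plus a random slope over
time (`ranef = "intercept_slope"`). Time is days since the subject's first
scan divided by 365.25; years keep slope variances on a sensible scale. The
observation minus fixed covariate effects and predicted random effects is
standardized by the divisor-$N$ RMS of the within-scanner residuals — the
same convention as the cross-sectional kernel, so the one tested EB kernel
serves both methods and the two agree exactly in the degenerate
one-scan-per-subject case. Boundary (singular) variance estimates are
accepted with a warning rather than refit; when every subject has a single
scan the subject variance is unidentified and is fixed at zero (OLS), which
is what makes the degenerate equivalence exact rather than
optimizer-dependent.

## The GAM-covariate variant

`harmonize_gamcombat()` lets designated covariates (age by default) enter
the standardization as penalized smooths: cubic B-splines with a
second-difference penalty, smoothing parameter chosen by generalized
cross-validation (GCV is deterministic, which matters for reproducible
pipelines). The penalty null space is the straight line, so linear truths
are recovered exactly and the method then coincides with the cross-sectional
harmonizer; the basis dimension defaults to 10 and is reduced with a warning
when the covariate has fewer distinct values. Smooth fits are computed on
the pooled data before scanner-effect estimation (two-stage structure);
scanner effects and parametric EB then proceed exactly as in the
cross-sectional kernel on the covariate-model residuals.

## The validation framework

**Cross-sectional** (`build_scanner_effect_report()`): the scan-rescan pair
coefficient of variation, $\mathrm{CoV} = 100\,\mathrm{sd}/\mathrm{mean}$,
is computed per subject for within-scanner pairs (random noise: the floor
harmonization cannot remove) and across-scanner pairs (noise plus scanner
effect). The across-scanner CoVs of each dataset are compared against the
common unharmonized within-scanner reference with a Welch t-test — the two
cohorts contain different subjects, so equal variances are not assumed; a
`student` flag provides the pooled-variance test. Holm adjustment is applied
within each dataset column; significant effects are labelled by Cohen's d at
the conventional 0.2/0.5/0.8 thresholds, with positive d meaning the scanner
adds variability.

**Longitudinal** (`triplet_covs()`, `method_effect_lmm()`,
`icc_agreement()`): each triplet subject has a reference scan and two
follow-ups years later, one on the reference scanner and one on a different
scanner. Because the two follow-ups are not simultaneous, the across-scanner
value is put on the within-scanner follow-up's date via the annualized rate:
$\mathrm{value}_{adj} = \mathrm{value}_{ref} + t_{within}\cdot
\mathrm{rate}_{across}$. The pair CoV of the within-scanner follow-up and
the adjusted across-scanner value is the per-subject scanner effect. Methods
are compared with `cov ~ method + (1 | subject)` (REML), unharmonized as the
reference level and 95% Wald intervals; we read the CoV as the *response* of
this model — the only reading consistent with "method as a fixed effect and
subject as a random effect" — and do not support the transposed
interpretation. No multiplicity correction is applied across methods here.
Whether harmonization destroys real biology is measured by the ICC between
across-scanner observed annualized rates and the same-scanner ground-truth
rates. The variant is ICC(A,1): two-way random effects, absolute agreement,
single measurement — agreement, not consistency, because a value of 1 must
mean the entire biological effect is recovered, and a constant offset should
be penalized. It is computed per ROI, matching the layout of an
agreement-by-region table.

**False positive rates** (`simulate_fpr()`): subjects are repeatedly
relabelled A/B by fair coin (not balanced by construction), and per ROI two
REML mixed models test the group intercept difference and the group x time
slope difference, controlling for age and sex with a subject random
intercept. Unadjusted p-values below the nominal level count as false
positives. Replicate seeds are `seed + replicate`, so all datasets see
identical label sequences and comparisons are paired; failed fits are
excluded from the denominator and reported rather than silently counted.
P-values are Wald by default (fast, deterministic); the group-inclusive
harmonization reading — where `group` is a harmonization covariate and
harmonization is re-run inside each replicate — is available through the
`harmonizers` argument, while the default reuses statically harmonized
datasets and records that mode in the result.

## The synthetic cohort generator

Real travelling-subject data cannot be redistributed, so every stage is
exercised on synthetic cohorts with known ground truth
(`simulate_cohort()`). The generative model decomposes scan-rescan
variability into its three canonical sources — a stable subject effect,
scanner effects, and scan-level noise:

$$y = \left(\mu_v\big(1 + s_{jv} + b^{age}_v(\mathrm{age}-50) + b^{sex}_v
  \mathrm{male} + b^{icv}_v z_{icv} + r_{jv} t\big) + \gamma_{iv}\right)
  \delta_i + \varepsilon,$$

additive-then-multiplicative by design so that recovery tests against the
ComBat model are well-posed. Choices a user should know about:

* **Scale-relative parameters.** Baselines are plausible adult ROI volumes
  (ventricles 25 cm³ ... supratentorial WM 440 cm³); subject SD, scanner
  offsets, covariate effects and rates are expressed as percent of baseline
  so one configuration spans ROIs of very different size. Subject effects
  and subject-level rate deviations are drawn per (subject, ROI).
* **Noise calibration.** The noise law is Gaussian. The scan-level SD is
  `baseline * noise_cov_percent / 100 / sqrt(2/pi)`: the sample SD of a
  pair of Gaussian draws is biased low by $c_4 = \sqrt{2/\pi}$, and the
  division makes the *expected scan-rescan pair CoV* equal the configured
  target — the quantity the validation framework actually measures. Default
  per-ROI targets span 0.9–3.4%, the range seen in scan-rescan studies of
  these metrics.
* **Cohort design.** Three sub-cohorts mirror a travelling-subject study:
  within-scanner pairs (< 180 days apart, strict), across-scanner pairs
  (< 180 days), and longitudinal triplets (two follow-ups > 365 days after
  the reference, within ~6 months of each other, one sharing the reference
  scanner). Default sizes (50 / 28 / 16 subjects, 5 scanners) are of the
  order of such studies; ages are uniform on 19–84 with ~50% male. ICV is
  log-normal with a male shift, giving a plausible positive covariate with
  known effect.
* **Scanner allocation** is round-robin over subjects, so every scanner is
  populated and estimable regardless of cohort size.
* **Reproducibility.** Every subject draws from an independent stream
  derived from the master seed: adding subjects never perturbs existing
  ones, and the two stock scenarios (`no_scanner_effect`,
  `scanner_effect`) share demographics at equal seed.

What the generator does **not** emulate: spatially correlated image noise,
scanner drift over time, non-Gaussian heavy-tailed measurement error,
missing scans, or correlation of scanner assignment with demographics
(confounding). Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
real-world pathology — in particular, harmonization under scanner–age
confounding is exactly the situation where the covariate-preserving model
matters most and where synthetic balance is most charitable.

## Numerical choices and degenerate inputs

* Intervals are integer day differences; "less than 180 days" and "more
  than 365 days" are strict. Subjects with more than two eligible scans
  contribute one pair per cohort: the shortest-interval qualifying pair,
  ties broken by earliest date then scan id — determinism over any claim of
  optimality.
* Sex is `M`/`F` in files and a 0/1 indicator (F = 0) in design matrices;
  group is A/B with A = 0.
* Degenerate statistics return defined values rather than crashing:
  both-cohorts-constant Welch comparisons give $t = 0, p = 1$ (equal means)
  or $p = 0$ (unequal); fully tied Friedman panels give statistic 0,
  $p = 1$; signed-rank values tied at the threshold are dropped before
  testing so the exact null distribution is used whenever possible.
* Rank-deficient designs error naming the collinear columns; scanners with
  a single scan error because the multiplicative effect is inestimable;
  EB with fewer than two features errors with a pointer to `eb = FALSE`.
* Covariates entering the longitudinal mixed models are centered and scaled
  internally (ICV is ~10⁶ mm³); the fitted covariate contribution is
  invariant to this.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at the
scale the package targets: cohorts of 25–94 subjects, 7 ROIs, 2–5 scanners;
false-positive-rate runs use 200 random group assignments for the
four-dataset comparison and 500 for the single-dataset calibration check,
sizes at which the binomial uncertainty of an FPR estimate (±1–2 percentage
points) is small relative to the 5%-vs-10% distinctions being made.

## Known limitations

* Voxel-wise harmonization, reference-batch ComBat and smooth-by-batch
  interactions are out of scope; the unit of data is the extracted feature
  table.
* Wald p-values slightly understate small-sample uncertainty in the FPR
  mixed models; the slope test at ~40 subjects runs a point or two above
  the nominal level even on perfectly null data, which is visible in the
  calibration results and inherent to the test, not to harmonization.
* The non-parametric EB path is quadratic in the number of features; for
  feature counts in the hundreds the parametric path is the practical
  default (and is the default).
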