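# scancombat

Feature-level harmonization of multi-scanner MRI measurements, with the
validation framework needed to decide whether harmonization is helping.

## The problem

Regional volumes, cortical thickness and diffusion metrics (FA, MD)
extracted from MRI depend on the scanner — the composite of site, machine
model and acquisition protocol — that produced the images. In multi-site
and longitudinal studies this *scanner effect* contaminates every
comparison. `scancombat` implements the ComBat family of statistical
harmonization methods and, just as importantly, the travelling-subject
machinery for quantifying what they fix and what they cost.

For feature *v*, scan *j* on scanner *i*:

    y_ijv = alpha_v + X_ij beta_v + gamma_iv + delta_iv * eps_ijv

with additive scanner offsets `gamma`, multiplicative factors `delta`, and
biological covariates `X` (age, sex, intracranial volume, time since first
scan). Per-scanner estimates are stabilized by empirical-Bayes shrinkage
across features (parametric normal/inverse-gamma priors, or a
non-parametric leave-one-feature-out empirical prior). Three harmonizers
share this kernel:

* `harmonize_neurocombat()` — cross-sectional ComBat,
* `harmonize_longcombat()` — per-feature linear mixed model with a subject
  random intercept (optionally + slope) before scanner-effect removal,
* `harmonize_gamcombat()` — penalized-spline (GCV) covariate adjustment for
  non-linear effects such as age.

Validation tools:

* `build_scanner_effect_report()` — scan-rescan coefficients of variation
  (CoV = 100·sd/mean per pair), within- vs across-scanner Welch tests,
  Holm adjustment, Cohen's d labels;
* `triplet_covs()`, `method_effect_lmm()`, `icc_agreement()` — longitudinal
  triplets, interval-adjusted follow-up discrepancies, mixed-model method
  comparison, and ICC(A,1) agreement of annualized rates with the
  same-scanner ground truth;
* `simulate_fpr()` — false positive rates under repeated random group
  assignment with mixed-model intercept/slope tests, plus
  `friedman_compare()` and `wilcoxon_exceeds_threshold()`;
* `simulate_cohort()` / `make_scenario()` — a travelling-subject cohort
  generator with known ground truth, so every stage is testable without
  protected patient data.

## Worked example

```r
library(scancombat)

covs <- c("age_years", "sex", "icv", "days_since_first_scan")
sim  <- simulate_cohort(make_scenario("scanner_effect", seed = 7))
coh  <- derive_cohorts(sim$table)   # within pairs, across pairs, triplets

tabs <- list(
  unharmonized = sim$table,
  neurocombat  = harmonize_neurocombat(sim$table, covs),
  longcombat   = harmonize_longcombat(sim$table, covs,
                                      ranef = "intercept_only"),
  gamcombat    = harmonize_gamcombat(sim$table, covs,
                                     smooth_terms = "age_years"))

report <- build_scanner_effect_report(tabs, coh)
aggregate(cbind(delta_cov, cohens_d) ~ dataset, report, mean)

icc <- icc_agreement(tabs, coh)
aggregate(icc ~ dataset, icc, median)
```

```
       dataset  delta_cov    cohens_d
1    gamcombat  0.2563333  0.25930458
2   longcombat -0.1356535 -0.08931045
3  neurocombat  0.3082746  0.28051186
4 unharmonized  8.4290126  3.11961080

       dataset        icc
1    gamcombat 0.58456795
2   longcombat 0.57469569
3  neurocombat 0.58777953
4 unharmonized 0.08803499
```

Reading the output: in the unharmonized data a second scan on a different
scanner adds ~8.4 CoV percentage points over the scan-rescan noise floor
(a large effect, Cohen's d ≈ 3.1), and the annualized rates of change
measured across scanners barely agree with the same-scanner ground truth
(median ICC ≈ 0.09 — the biological signal is mostly lost). After any of
the three harmonization methods the added variability is small (|d| ≤ 0.3)
and rate agreement is restored to ICC ≈ 0.58.

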