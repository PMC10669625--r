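---
title: "Dynamic breath-washout analysis: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic breath-washout analysis: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathkin)
```

`breathkin` analyses dynamic breath tests in which a volatile probe compound
(limonene, a dietary monoterpene with high hepatic extraction) is ingested and
its washout is followed in exhaled breath. Because limonene is flow-limited,
its systemic availability — and therefore its breath levels — rises sharply
when hepatic extraction falls or when portal blood bypasses the liver through
portosystemic shunts, while its elimination slope barely moves. That makes the
washout curve a functional read-out of hepatic first pass, and the package
implements the full analysis chain around that idea: cohort simulation,
non-compartmental kinetics, per-timepoint diagnostic evaluation, block
correlation with clinical severity scores, and the supporting inference.

## The washout model

A subject's breath amount (ng per standardized 400 mL sample) after an oral
dose $D$ follows the one-compartment first-order (Bateman) solution

$$A(t) = s \, F \, D \, \frac{k_a}{k_a - k_e}\left(e^{-k_e t} - e^{-k_a t}\right),$$

with absorption rate $k_a$, elimination rate $k_e$, a dimensionless
blood-to-breath sampling scale $s$, and systemic availability $F$. When
$|k_a - k_e|$ falls below a relative tolerance of $10^{-8}$ the degenerate
limit $s F D k_a t e^{-k_a t}$ is used explicitly, so the function is
continuous in its parameters.

Availability comes from the well-stirred liver model with shunting:
$E = c/(1+c)$ for intrinsic-clearance-to-flow ratio $c$, and

$$F = f_{abs}\,\bigl(\text{shunt} + (1-\text{shunt})(1-E)\bigr),$$

monotone increasing in shunt and decreasing in $c$. A healthy liver with
$c \approx 9$ extracts ~90% of the absorbed dose; cirrhosis lowers $c$ and
adds shunt, multiplying $F$ several-fold. Blood levels are never modelled
separately: the breath amount is the unit of record, and the blood:air
partition is folded into `breath_scale`.

## What the synthetic cohort emulates

`sim_config()` defaults define the study conditions: two groups of 29, a
100 mg dose (1e8 ng), sampling at 0/20/40/60/90/120 min, quantification limit
1.18 ng, ~15% multiplicative measurement noise, and a small (2%) rate of
missing samples. Within the cirrhosis group a latent severity variable drives
shunt upward and intrinsic clearance downward, and also lowers platelets,
enlarges the spleen and raises the probability of an ultrasound
portal-hypertension flag — so bioavailability and the clinical proxies
co-segregate, as they must for the flag comparisons to be meaningful.
Thrombocytopenia is defined as platelets below 150×10⁹/L and splenomegaly as
spleen length above 12 cm, exactly consistent with the generated covariates.

Calibration targets were the published group summaries for this kind of
study: control Cmax of a few hundred ng with an IQR ratio near 2.5, a
~3.5–4.5-fold cirrhosis elevation of Cmax and AUC with unchanged slope
distribution (the flow-limited signature), terminal ln-intercepts near 6.9
(control) and 8.4 (cirrhosis), roughly a fifth of control baselines below the
quantification limit, and a baseline-level discrimination around AUROC 0.83.
Two generator choices deserve explanation:

* **Fast absorption.** The default $k_a$ (median 0.18/min, log-sd 0.25;
  continuous peak ≈ 13 min, observed grid Tmax 20 min) was chosen so that
  absorption is essentially complete by the first post-peak sample. The
  terminal fit starts at the observed Tmax, and with slower absorption the
  Bateman tail biases the fitted slope visibly shallow; with the fast default
  the median slope recovery error stays within a few percent. The cost is a
  Tmax distribution more concentrated at 20 min than a real cohort's; we
  accept that, since slope recovery is a stated accuracy requirement while
  the Tmax frequency split is descriptive. The dose formulation's true
  absorption rate is unknown — $k_a$ is a free calibration choice consistent
  with peaks in the 20–40 min window.
* **Availability-coupled baseline.** The pre-dose (dietary) baseline is drawn
  log-normally per group and then scaled by the subject's availability
  relative to the group-typical availability, because dietary limonene
  undergoes the same first pass as the dose. Without this coupling one cannot
  simultaneously have wide within-group Cmax spreads, a universal >100-fold
  post-dose spike over baseline, and baseline discrimination near AUROC 0.83;
  with it, all three hold.

MELD, FIB4 and APRI are generated in the cirrhosis group as linear functions
of ln AUC plus Gaussian noise, with coupling strength MELD > FIB4 > APRI, and
independently of AUC in controls — so the control-group block correlation is
null by construction. About 10% of subjects lack one score, exercising the
complete-case path downstream.

What the generator does **not** emulate: multi-exponential or
physiologically-based kinetics, adipose accumulation of the probe, inhaled
(environmental) exposure routes, informative missingness, assay drift or
batch effects, and any real covariance structure among the clinical labs
beyond the single severity factor. Passing tests on synthetic cohorts
therefore demonstrate correctness of the analysis machinery under the stated
model, not clinical performance on real data.

## Non-compartmental kinetics

* `compute_cmax_tmax()` takes the maximum *observed* post-dose amount; the
  baseline sample is excluded and ties go to the earliest time.
* `fit_terminal_slope()` regresses log amount on time using every point from
  Tmax (inclusive) onward, requiring at least three. The intercept is
  reported at $t = 0$ on the natural-log scale. Natural log is the default
  deliberately: published intercept values of ~6.9 for controls are consistent
  with Cmax in the hundreds of ng only on the natural scale
  ($e^{6.9} \approx 990$, whereas $10^{6.9}$ is eight million) — tables in
  this literature sometimes label the quantity "log10" regardless. A
  `log_base` argument exposes the alternative.
* Subjects with fit $R^2 \le 0.8$ are kept for level summaries (Cmax, AUC)
  but excluded from slope/intercept group comparisons, mirroring the standard
  screening of non-log-linear washouts.
* `trapezoid_auc()` integrates linearly over the observed points in 0–90 min.
  If the window edge falls between observations the edge value is linearly
  interpolated from its flanking observations, which keeps the integral
  additive over sub-windows; a subject whose samples do not span the window
  gets a missing AUC rather than an extrapolated one. LOQ-imputed baselines
  enter at the imputed value — imputation, not deletion, is the convention
  for this assay.

## Diagnostic evaluation

Each timepoint (and Cmax) is scored by univariable logistic regression on the
log amount. Out-of-sample AUROC, sensitivity and specificity are estimated by
five repeated stratified 80/20 train/test splits: the model and its Youden
threshold come from the training split, metrics from the held-out split, and
the report gives mean ± sd across repeats (sd, not se — the label is
explicit). Five-fold stratified cross-validation is available via
`scheme = "kfold"` for users who read "5-fold" literally; the repeated-split
default matches the practice of averaging test-set estimates.

Predictive values and likelihood ratios are intentionally *not* split-averaged:
they are computed from the whole-cohort confusion matrix at the full-fit
Youden threshold, which is how such tables are normally assembled (their
printed values are exact ratios of small integers at the cohort size). Both
families of numbers appear in `report.json`, explicitly labelled. Because
logistic scoring of one feature is monotone, the operating point is also
reported back on the ng scale.

ROC construction sweeps the unique score values with the rule
score ≥ threshold ⇒ positive; tied scores earn half credit, so the trapezoid
area equals the mid-rank $U/(n_1 n_2)$ identity exactly, which the tests
assert to machine precision. Youden ties are broken toward higher
specificity, and the reported threshold is the midpoint of the score gap it
lies in (for separated groups: the midpoint of the class gap). Complete
separation of the logistic fit is detected and handled by a small ridge
penalty (1e-4 on the slope) with damped Newton iterations, flagged in the
output rather than silently diverging. Degenerate confusion-matrix ratios
(zero denominators) return a classed warning and an explicit `Inf`/`NaN`,
never a silent `NaN`.

## Canonical correlation

`canonical_correlation()` standardizes both blocks, drops incomplete rows
(counting them), and solves the canonical problem through R's QR-based
routine; the tests verify agreement with the eigen formulation of
$S_{xx}^{-1} S_{xy} S_{yy}^{-1} S_{yx}$ to 1e-8 and invariance under
invertible affine transforms of either block. Loadings are correlations of
the original variables with the first canonical variate; the sign is fixed so
the dominant y-block loading is positive (both variates flip together).
Significance of the first dimension uses Bartlett's chi-squared
approximation, $-(n - 1 - (p+q+1)/2)\ln\Lambda$ with $\Lambda = \prod(1 -
r_i^2)$ on $pq$ degrees of freedom, which is the default reported p-value;
Rao's F approximation is computed alongside for users who prefer it. Later
dimensions are exposed in the sequential table but not headlined — with a
one-dimensional x block there is only one dimension anyway.

## Inference machinery

`mann_whitney_u()` computes U from mid-ranks. For pooled samples of at most
16 without ties the two-sided p-value is exact (the cutoff is an argument);
otherwise the normal approximation with tie and continuity corrections is
used. The tests check the exact route against a full enumeration of
$\binom{n_1+n_2}{n_1}$ allocations and the approximate route against a
100,000-draw permutation oracle.

The age-confounder check fits
`log(limonene) ~ group + age + factor(timepoint)` with a random intercept per
subject, by maximum likelihood (not REML) so Wald z-tests and likelihood
comparisons are coherent; REML is an option. The fixed-effect design is a
documented choice — the analysis requirement names only age and the
longitudinal structure. Balanced-design variance components are verified
against the closed-form ML solution, and the degenerate no-subject-effect
limit against OLS.

## Numerical conventions and degenerate inputs

* Rates, fractions and window parameters are validated up front; errors carry
  classed conditions (`breathkin_invalid_parameter`,
  `breathkin_insufficient_data`, `breathkin_incomplete_window`,
  `breathkin_rank_deficient`, `breathkin_class_too_small`,
  `breathkin_stage_failure`) so callers can branch on them.
* The $k_a = k_e$ degeneracy switches to the closed-form limit at relative
  tolerance 1e-8.
* Rank deficiency in a CCA block or an LMM design is reported with the
  offending column named.
* Every stochastic stage takes an explicit seed; `simulate_cohort()` and
  `evaluate_timepoints()` restore the global RNG state, and `run_pipeline()`
  is digest-for-digest reproducible at a fixed seed.

## Problem sizes used by the test suite

The suite exercises the package at deliberately modest scales chosen to make
the statistical assertions sharp but cheap: study-scale cohorts of 29 + 29
(50 seeded replicates for the headline-pattern check), parameter-recovery
cohorts of 200 per group, 1000 random instances for the AUROC–U identity,
500 null replicates at n = 500 for the CCA calibration, and full enumeration
oracles up to 6 + 6 for the exact Mann–Whitney test. `scripts/acceptance.R`
re-runs the study-scale pipeline end to end at a user-supplied seed.

## Known limitations

AUC is a within-study proxy of bioavailability, not an absolute one — no
blood sampling is modelled, so `breath_scale` is unidentifiable and only
ratios and discriminations are meaningful. The terminal fit window (from the
observed Tmax) is a fixed rule: no automatic terminal-phase point selection
is attempted, and with slow absorption the fitted slope will under-estimate
the elimination rate. AUC is never extrapolated to infinity. The classifier
is strictly univariable; combining timepoints or compounds is out of scope,
as are calibration curves and external validation.
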