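# breathkin

Analysis of **dynamic breath tests** that probe liver function with an
ingested volatile compound. Limonene, a dietary monoterpene, is almost
completely extracted by a healthy liver on first pass; in cirrhosis, reduced
intrinsic clearance and portosystemic shunting let far more of an oral dose
reach the systemic circulation and appear in exhaled breath. Following the
breath washout after a standardized 100 mg dose therefore turns a
gas-chromatography breath measurement into a functional first-pass assay —
and a candidate non-invasive screen for cirrhosis, which is typically
diagnosed only after decompensation.

`breathkin` is aimed at researchers designing or analysing such studies. It
provides, as a tidyverse-style R package:

* a **synthetic cohort generator** (`sim_config()`, `simulate_cohort()`)
  built on the one-compartment oral-dose (Bateman) model
  `A(t) = s·F·D·ka/(ka−ke)·(e^(−ke·t) − e^(−ka·t))` with well-stirred
  first-pass availability `F = f_abs·(shunt + (1−shunt)/(1+cl))`,
  limit-of-quantification censoring at 1.18 ng, and clinical metadata
  (MELD/FIB4/APRI, platelets, spleen, portal-hypertension flags) coupled to a
  latent disease severity;
* **non-compartmental kinetics** (`nca()`, `summarize_kinetics()`): Cmax and
  Tmax, the terminal log-linear slope and intercept with an R² > 0.8
  log-linearity screen, and trapezoidal AUC over 0–90 min;
* **per-timepoint diagnostic evaluation** (`evaluate_timepoints()`):
  logistic scoring of each timepoint and Cmax, repeated stratified 80/20
  splits for AUROC/sensitivity/specificity (mean ± sd), Youden operating
  points, and whole-cohort predictive values and likelihood ratios;
* **canonical correlation** (`canonical_correlation()`,
  `cca_auc_vs_scores()`) of breath bioavailability (ln AUC) against the
  MELD/FIB4/APRI block, with canonical loadings and Bartlett/Rao tests;
* **inference utilities**: mid-rank Mann–Whitney U with exact small-sample
  p-values (`mann_whitney_u()`), AUC comparisons by portal-hypertension
  proxies (`compare_auc_by_flag()`), and a random-intercept mixed model for
  the longitudinal age-confounder check (`age_confounder_check()`);
* an end-to-end, seed-reproducible **pipeline** (`run_pipeline()`) and a thin
  command-line front-end (`inst/cli/breathkin.R`).

Fitted objects come with `tidy()`/`glance()` methods and `autoplot()`/
`plot_*()` figures. See the methods vignette
(`vignettes/breathkin-methods.Rmd`) for the models, default calibration and
its rationale, and known limitations.

## Worked example

```r
library(breathkin)

cohort <- simulate_cohort(sim_config(seed = 1))   # 29 controls + 29 cirrhosis
kin    <- nca(cohort$washout)
summarize_kinetics(kin)
#> Washout kinetic parameters by group (median [IQR])
#>      parameter                       cirrhosis                         control      p_value
#>        cmax_ng                2673 [1580-4626]             644.7 [429.2-843.3] 2.365194e-08
#>         c0_log             8.547 [7.914-8.938]               6.952 [6.7-7.358] 8.716651e-09
#>       auc_0_90 1.223e+05 [7.607e+04-2.005e+05] 2.719e+04 [2.027e+04-3.548e+04] 1.257256e-08
#>  slope_per_min    -0.02567 [-0.02961--0.02347]    -0.02558 [-0.02811--0.02372] 5.441824e-01
```

The flow-limited signature is all there: the cirrhosis group's peak amount,
terminal intercept and AUC are elevated about four-fold (p ≈ 1e-8), while the
washout slope — the elimination rate — does not differ between groups
(p = 0.54). Classification sharpens after dosing:

```r
rep <- evaluate_timepoints(cohort$washout, kin, cohort$subjects, seed = 1)
rep[rep$feature %in% c("0", "60"),
    c("feature", "auroc_mean", "sens_mean", "spec_mean", "ppv_pct", "npv_pct")]
#>   feature auroc_mean sens_mean spec_mean ppv_pct  npv_pct
#> 1       0  0.7250000 0.4333333       0.9     100 74.35897
#> 2      60  0.9333333 0.7333333       0.9     100 82.85714
```

The pre-dose baseline separates the groups only moderately (held-out AUROC
0.73), whereas the 60-minute post-dose sample reaches AUROC 0.93 at its
Youden operating point — the dynamic test outperforms the static one. Within
the cirrhosis group, bioavailability tracks disease severity:

```r
cca_auc_vs_scores(kin, cohort$subjects)
#> Canonical correlation (p = 1, q = 3, n = 26 complete, 3 dropped)
#>   r: 0.712
#>   first dimension: Wilks' Lambda = 0.4937, Bartlett chi2(3) = 15.88, p = 0.001199
#>   y loadings: meld 0.76, fib4 0.45, apri 0.52
```

ln AUC and the clinical scoring block share a significant first canonical
dimension (r₁ = 0.71, p ≈ 0.001), with MELD carrying the largest loading —
the severity score contributes most to the correlation. Subjects with
incomplete metadata are dropped and counted.

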